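compound,cell_line,retinoblastoma,effector_uM,ic50
Nocodazole,HL-60/RV+,FALSE,0,0.24
Nocodazole,HL-60/RV+,FALSE,30,>100
Nocodazole,HL-60/RV+,FALSE,80,>100
Nocodazole,OCM290,FALSE,0,1.8
Nocodazole,OCM290,FALSE,30,>100
Nocodazole,OCM290,FALSE,80,>100
Nocodazole,BE(2)-C,FALSE,0,0.35
Nocodazole,BE(2)-C,FALSE,30,0.83
Nocodazole,BE(2)-C,FALSE,80,>100
Nocodazole,NCC-RbC-60,TRUE,0,0.23
Nocodazole,NCC-RbC-60,TRUE,30,>100
Nocodazole,NCC-RbC-60,TRUE,80,>100
Colchicine,HL-60/RV+,FALSE,0,1.06
Colchicine,HL-60/RV+,FALSE,30,>100
Colchicine,HL-60/RV+,FALSE,80,>100
Colchicine,OCM290,FALSE,0,0.015
Colchicine,OCM290,FALSE,30,>100
Colchicine,OCM290,FALSE,80,>100
Colchicine,MDA-MB-231,FALSE,0,>100
Colchicine,MDA-MB-231,FALSE,30,>100
Colchicine,MDA-MB-231,FALSE,80,>100
Colchicine,NCC-RbC-60,TRUE,0,0.65
Colchicine,NCC-RbC-60,TRUE,30,3.2
Colchicine,NCC-RbC-60,TRUE,80,0.74
Vincristine sulfate,HL-60/RV+,FALSE,0,3.1
Vincristine sulfate,HL-60/RV+,FALSE,30,>100
Vincristine sulfate,HL-60/RV+,FALSE,80,>100
Vincristine sulfate,OCM290,FALSE,0,0.040
Vincristine sulfate,OCM290,FALSE,30,>100
Vincristine sulfate,OCM290,FALSE,80,>100
Vincristine sulfate,MDA-MB-231,FALSE,0,>100
Vincristine sulfate,MDA-MB-231,FALSE,30,>100
Vincristine sulfate,MDA-MB-231,FALSE,80,>100
Vincristine sulfate,NCC-RbC-60,TRUE,0,0.010
Vincristine sulfate,NCC-RbC-60,TRUE,30,>100
Vincristine sulfate,NCC-RbC-60,TRUE,80,1.7
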