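role,compound,cell_line,effector_uM,ic50
agonist,Berberine chloride,OCM290,0,10*
agonist,Berberine chloride,OCM290,30,>100*
agonist,Berberine chloride,OCM290,80,>100*
agonist,Perphenazine,OCM290,0,19*
agonist,Perphenazine,OCM290,30,38*
agonist,Perphenazine,OCM290,80,26*
agonist,Avermectin B1,OCM290,0,6.9*
agonist,Avermectin B1,OCM290,30,>100*
agonist,Avermectin B1,OCM290,80,19*
agonist,Phorbol 12-myristate 13 acetate,OCM290,0,11*
agonist,Phorbol 12-myristate 13 acetate,OCM290,30,21*
agonist,Phorbol 12-myristate 13 acetate,OCM290,80,17*
agonist,Budesonide,OCM290,0,>100
agonist,Budesonide,OCM290,30,>100
agonist,Budesonide,OCM290,80,>100
agonist,Piperazine carbazole ethanol derivative,OCM290,0,3.8
agonist,Piperazine carbazole ethanol derivative,OCM290,30,5.2*
agonist,Piperazine carbazole ethanol derivative,OCM290,80,6.2*
agonist,Triamterene,OCM290,0,27*
agonist,Triamterene,OCM290,30,>100
agonist,Triamterene,OCM290,80,>100
agonist,Lercanidipine,OCM290,0,8.7
agonist,Lercanidipine,OCM290,30,>100*
agonist,Lercanidipine,OCM290,80,>100*
antagonist,Nocodazole,OCM290,0,0.19*
antagonist,Nocodazole,OCM290,30,>100*
antagonist,Nocodazole,OCM290,80,>100
antagonist,Chelidonine,OCM290,0,2.0*
antagonist,Chelidonine,OCM290,30,>100*
antagonist,Chelidonine,OCM290,80,>100
antagonist,Albendazole,OCM290,0,0.93
antagonist,Albendazole,OCM290,30,>100*
antagonist,Albendazole,OCM290,80,>100*
antagonist,ZM 447439,OCM290,0,0.55
antagonist,ZM 447439,OCM290,30,>100*
antagonist,ZM 447439,OCM290,80,>100*
antagonist,Tolperisone,OCM290,0,14
antagonist,Tolperisone,OCM290,30,34*
antagonist,Tolperisone,OCM290,80,58*
antagonist,PALDA,OCM290,0,>100*
antagonist,PALDA,OCM290,30,>100
antagonist,PALDA,OCM290,80,>100
antagonist,SKF 96365,OCM290,0,2.7
antagonist,SKF 96365,OCM290,30,6.0*
antagonist,SKF 96365,OCM290,80,37*
antagonist,Floxuridine,OCM290,0,0.16
antagonist,Floxuridine,OCM290,30,>100
antagonist,Floxuridine,OCM290,80,>100
antagonist,Thioguanosine,OCM290,0,7.1
antagonist,Thioguanosine,OCM290,30,>100*
antagonist,Thioguanosine,OCM290,80,>100*
antagonist,Quinidine,OCM290,0,>100*
antagonist,Quinidine,OCM290,30,>100
antagonist,Quinidine,OCM290,80,>100*
antagonist,LY 171883,OCM290,0,>100
antagonist,LY 171883,OCM290,30,>100
antagonist,LY 171883,OCM290,80,>100
antagonist,Caffeic acid phenethyl ester,OCM290,0,18*
antagonist,Caffeic acid phenethyl ester,OCM290,30,>100*
antagonist,Caffeic acid phenethyl ester,OCM290,80,>100
antagonist,IKK 16,OCM290,0,1.3
antagonist,IKK 16,OCM290,30,4.4
antagonist,IKK 16,OCM290,80,4.6
additional,Vincristine sulfate,OCM290,0,0.010*
additional,Vincristine sulfate,OCM290,30,>100*
additional,Vincristine sulfate,OCM290,80,>100*
additional,Colchicine,OCM290,0,0.020
additional,Colchicine,OCM290,30,>100*
additional,Colchicine,OCM290,80,>100*
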