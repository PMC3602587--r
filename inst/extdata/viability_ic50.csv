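role,compound,cell_line,effector_uM,ic50
agonist,Berberine chloride,Y79,0,24*
agonist,Berberine chloride,Y79,30,15
agonist,Berberine chloride,Y79,80,8.6
agonist,Berberine chloride,RB355,0,59*
agonist,Berberine chloride,RB355,30,23
agonist,Berberine chloride,RB355,80,6.8
agonist,Perphenazine,Y79,0,32
agonist,Perphenazine,Y79,30,27
agonist,Perphenazine,Y79,80,16
agonist,Perphenazine,RB355,0,25
agonist,Perphenazine,RB355,30,19
agonist,Perphenazine,RB355,80,9.8
agonist,Avermectin B1,Y79,0,>100*
agonist,Avermectin B1,Y79,30,>100
agonist,Avermectin B1,Y79,80,>100
agonist,Avermectin B1,RB355,0,55*
agonist,Avermectin B1,RB355,30,47*
agonist,Avermectin B1,RB355,80,60*
agonist,Phorbol 12-myristate 13 acetate,Y79,0,>100
agonist,Phorbol 12-myristate 13 acetate,Y79,30,>100
agonist,Phorbol 12-myristate 13 acetate,Y79,80,>100*
agonist,Phorbol 12-myristate 13 acetate,RB355,0,>100
agonist,Phorbol 12-myristate 13 acetate,RB355,30,>100
agonist,Phorbol 12-myristate 13 acetate,RB355,80,67*
agonist,Budesonide,Y79,0,>100
agonist,Budesonide,Y79,30,>100
agonist,Budesonide,Y79,80,>100*
agonist,Budesonide,RB355,0,>100
agonist,Budesonide,RB355,30,>100
agonist,Budesonide,RB355,80,>100*
agonist,Piperazine carbazole ethanol derivative,Y79,0,9.2
agonist,Piperazine carbazole ethanol derivative,Y79,30,7.9
agonist,Piperazine carbazole ethanol derivative,Y79,80,7.4
agonist,Piperazine carbazole ethanol derivative,RB355,0,12
agonist,Piperazine carbazole ethanol derivative,RB355,30,8.7
agonist,Piperazine carbazole ethanol derivative,RB355,80,7.0
agonist,Triamterene,Y79,0,>100*
agonist,Triamterene,Y79,30,>100*
agonist,Triamterene,Y79,80,>100*
agonist,Triamterene,RB355,0,33*
agonist,Triamterene,RB355,30,>100*
agonist,Triamterene,RB355,80,>100*
agonist,Lercanidipine,Y79,0,38*
agonist,Lercanidipine,Y79,30,36*
agonist,Lercanidipine,Y79,80,38*
agonist,Lercanidipine,RB355,0,19
agonist,Lercanidipine,RB355,30,57*
agonist,Lercanidipine,RB355,80,33*
antagonist,Nocodazole,Y79,0,34*
antagonist,Nocodazole,Y79,30,21*
antagonist,Nocodazole,Y79,80,5.6*
antagonist,Nocodazole,RB355,0,1.1
antagonist,Nocodazole,RB355,30,0.53*
antagonist,Nocodazole,RB355,80,>100*
antagonist,Chelidonine,Y79,0,6.8*
antagonist,Chelidonine,Y79,30,7.9*
antagonist,Chelidonine,Y79,80,4.9*
antagonist,Chelidonine,RB355,0,1.6
antagonist,Chelidonine,RB355,30,1.3*
antagonist,Chelidonine,RB355,80,>100*
antagonist,Albendazole,Y79,0,>100*
antagonist,Albendazole,Y79,30,>100*
antagonist,Albendazole,Y79,80,>100*
antagonist,Albendazole,RB355,0,20*
antagonist,Albendazole,RB355,30,23*
antagonist,Albendazole,RB355,80,>100*
antagonist,ZM 447439,Y79,0,25*
antagonist,ZM 447439,Y79,30,6.3*
antagonist,ZM 447439,Y79,80,4.1*
antagonist,ZM 447439,RB355,0,1.4
antagonist,ZM 447439,RB355,30,1.4
antagonist,ZM 447439,RB355,80,8.4
antagonist,Tolperisone,Y79,0,74*
antagonist,Tolperisone,Y79,30,67*
antagonist,Tolperisone,Y79,80,35*
antagonist,Tolperisone,RB355,0,>100*
antagonist,Tolperisone,RB355,30,73*
antagonist,Tolperisone,RB355,80,49*
antagonist,PALDA,Y79,0,5.2
antagonist,PALDA,Y79,30,13
antagonist,PALDA,Y79,80,10
antagonist,PALDA,RB355,0,6.1
antagonist,PALDA,RB355,30,15
antagonist,PALDA,RB355,80,15
antagonist,SKF 96365,Y79,0,>100*
antagonist,SKF 96365,Y79,30,51*
antagonist,SKF 96365,Y79,80,58*
antagonist,SKF 96365,RB355,0,8.1
antagonist,SKF 96365,RB355,30,9.5
antagonist,SKF 96365,RB355,80,82*
antagonist,Floxuridine,Y79,0,0.44
antagonist,Floxuridine,Y79,30,0.43
antagonist,Floxuridine,Y79,80,0.45
antagonist,Floxuridine,RB355,0,0.82
antagonist,Floxuridine,RB355,30,0.76
antagonist,Floxuridine,RB355,80,1.4
antagonist,Thioguanosine,Y79,0,1.04
antagonist,Thioguanosine,Y79,30,1.03
antagonist,Thioguanosine,Y79,80,0.79
antagonist,Thioguanosine,RB355,0,1.4
antagonist,Thioguanosine,RB355,30,1.1
antagonist,Thioguanosine,RB355,80,0.78
antagonist,Quinidine,Y79,0,>100
antagonist,Quinidine,Y79,30,>100
antagonist,Quinidine,Y79,80,>100*
antagonist,Quinidine,RB355,0,74*
antagonist,Quinidine,RB355,30,>100
antagonist,Quinidine,RB355,80,61*
antagonist,LY 171883,Y79,0,>100
antagonist,LY 171883,Y79,30,>100
antagonist,LY 171883,Y79,80,>100
antagonist,LY 171883,RB355,0,>100
antagonist,LY 171883,RB355,30,>100
antagonist,LY 171883,RB355,80,>100
antagonist,Caffeic acid phenethyl ester,Y79,0,>100*
antagonist,Caffeic acid phenethyl ester,Y79,30,>100*
antagonist,Caffeic acid phenethyl ester,Y79,80,75*
antagonist,Caffeic acid phenethyl ester,RB355,0,21*
antagonist,Caffeic acid phenethyl ester,RB355,30,49*
antagonist,Caffeic acid phenethyl ester,RB355,80,36*
antagonist,IKK 16,Y79,0,3.6
antagonist,IKK 16,Y79,30,4.8
antagonist,IKK 16,Y79,80,6.1
antagonist,IKK 16,RB355,0,5.9
antagonist,IKK 16,RB355,30,6.5
antagonist,IKK 16,RB355,80,6.6
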