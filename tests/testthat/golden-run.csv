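t,x,y,mass,energy
 0,15.500000000000000,15.500000000000000,156.52402914035770,38.302739886503673
 5,15.508424175432737,15.514058542061365,156.52402914035781,26.988600759611927
10,15.481709221319385,15.561788997903770,156.52402914035787,26.929439572020762
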