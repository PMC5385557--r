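antecedent,consequent,antecedent_negated,consequent_negated,support,confidence,interest,context_adjusted,interval,context_rainfall
"is_a(Apd,>=X1) & is_a(Pheh,>=X2) & diff_of(Aio.Rps,>X3) & color_of(soil,Y1)","found(MP,true)",FALSE,FALSE,8,NA,NA,FALSE,1,250
"is_a(Apd,>=X1) & is_a(Pheh,>=X2) & diff_of(Aio.Rps,>X3) & color_of(soil,Y1) & is_a(Ni,>=X3)","found(MP,true)",FALSE,FALSE,6,NA,NA,FALSE,1,250
"is_a(Apd,>=X1) & is_a(Pheh,<=X2) & diff_of(Aio.Rps,>X3) & color_of(soil,Y1)","found(MP,true)",FALSE,FALSE,6,NA,NA,FALSE,1,450
"is_a(Apd,>=X1) & is_a(Pheh,<=X2) & is_a(Aio,>X4) & color_of(soil,Y1)","found(MP,true)",FALSE,FALSE,8,NA,NA,FALSE,1,370
"is_a(Apd,>=X1) & is_a(Pheh,>=X2) & diff_of(Aio.Rps,>X3) & color_of(soil,Y1)","found(MP,true)",FALSE,FALSE,7,NA,NA,FALSE,2,250
"is_a(Apd,>=X1) & is_a(Pheh,>=X2) & diff_of(Aio.Rps,>X3) & color_of(soil,Y1) & is_a(Ni,>=X3)","found(MP,true)",FALSE,FALSE,4,NA,NA,FALSE,2,250
"is_a(Apd,>=X1) & is_a(Pheh,>=X2) & diff_of(Aio.Rps,>X3) & color_of(soil,Y1)","found(MP,true)",FALSE,FALSE,4,NA,NA,FALSE,2,250
"is_a(Apd,>=X1) & is_a(An,>=X5) & close_to(Prospect,rock)","found(MP,true)",FALSE,FALSE,6,NA,NA,FALSE,3,250
"is_a(Apd,>=X1) & is_a(Pheh,<=X2) & diff_of(Aio.Rps,>X3) & color_of(soil,Y1) & is_a(Ni,>=X3)","found(MP,true)",FALSE,FALSE,5,NA,NA,FALSE,3,450
"is_a(Apd,>=X1) & is_a(Pheh,>=X2) & diff_of(Aio.Rps,>X3) & color_of(soil,Y1)","found(MP,true)",FALSE,FALSE,5,NA,NA,FALSE,4,250
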