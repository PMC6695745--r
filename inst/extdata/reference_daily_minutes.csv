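age_category,method,level,minutes,pct
children,vo2net,SED,661,64.8
children,vo2net,LPA,142,14.0
children,vo2net,MPA,154,15.1
children,vo2net,VPA,47,4.6
children,vo2net,VVPA,15,1.5
adolescents,vo2net,SED,786,77.1
adolescents,vo2net,LPA,119,11.7
adolescents,vo2net,MPA,99,9.7
adolescents,vo2net,VPA,12,1.1
adolescents,vo2net,VVPA,4,0.4
adults_young,vo2net,SED,826,81.0
adults_young,vo2net,LPA,119,11.7
adults_young,vo2net,MPA,71,7.0
adults_young,vo2net,VPA,2,0.2
adults_young,vo2net,VVPA,1,0.1
adults_old,vo2net,SED,821,80.5
adults_old,vo2net,LPA,128,12.5
adults_old,vo2net,MPA,69,6.8
adults_old,vo2net,VPA,2,0.2
adults_old,vo2net,VVPA,0,0.0
children,met,SED,710,69.6
children,met,LPA,170,16.7
children,met,MPA,125,12.3
children,met,VPA,10,1.0
children,met,VVPA,5,0.5
adolescents,met,SED,814,77.8
adolescents,met,LPA,123,12.0
adolescents,met,MPA,78,7.6
adolescents,met,VPA,3,0.3
adolescents,met,VVPA,2,0.2
adults_young,met,SED,826,81.0
adults_young,met,LPA,119,11.7
adults_young,met,MPA,71,7.0
adults_young,met,VPA,2,0.2
adults_young,met,VVPA,1,0.1
adults_old,met,SED,821,80.5
adults_old,met,LPA,128,12.5
adults_old,met,MPA,69,6.8
adults_old,met,VPA,2,0.2
adults_old,met,VVPA,0,0.0
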