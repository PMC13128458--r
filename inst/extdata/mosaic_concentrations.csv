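variable,ice_type,compartment,mean,se,n
chla,ridge,interior,2.6,0.9,23
chla,ridge,exterior,19,9,16
chla,ridge,voids,3,1,3
chla,ridge,bottom,1.2,0.2,5
chla,fyi,interior,0.9,0.1,160
chla,fyi,bottom,3.9,0.9,5
chla,syi,interior,0.8,0.1,68
chla,syi,bottom,3.1,0.7,4
poc,ridge,interior,420,60,21
poc,ridge,exterior,410,100,6
poc,ridge,voids,100,30,3
poc,ridge,bottom,390,60,5
poc,fyi,interior,280,30,54
poc,fyi,bottom,950,220,5
poc,syi,interior,760,70,73
poc,syi,bottom,470,100,4
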