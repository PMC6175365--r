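id,source,habitat,form,a,b,c0,c1,c2,c3,provenance
chave14_of,Chave et al. 2014 (height-free),old_growth,log_poly,NA,NA,-1.803,2.673,-0.0299,0.976,transcribed
dung_of,Dung et al. (stand-in),old_growth,power,0.0509,1.30,NA,NA,NA,NA,synthetic
chave14_sec,Chave et al. 2014 (height-free),secondary,log_poly,NA,NA,-1.803,2.673,-0.0299,0.976,transcribed
ketterings_sec,Ketterings et al. 2001 (adapted to shared form),secondary,power,0.11,1.31,NA,NA,NA,NA,adapted
vanbreugel_sec,van Breugel et al. (stand-in),secondary,log_poly,NA,NA,-1.863,2.208,0,0.787,synthetic
schnitzer_li,Schnitzer et al. 2006,liana,log_poly,NA,NA,-1.484,2.657,0,0,transcribed
putz_li,Putz (stand-in),liana,liana_power,0.223,2.26,NA,NA,NA,NA,synthetic
gehring_li,Gehring et al. (stand-in),liana,liana_power,0.18,2.40,NA,NA,NA,NA,synthetic
sierra_li,Sierra et al. (stand-in),liana,liana_power,0.26,2.20,NA,NA,NA,NA,synthetic
addofordjour_li,Addo-Fordjour & Rahmad (stand-in),liana,liana_power,0.20,2.34,NA,NA,NA,NA,synthetic
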