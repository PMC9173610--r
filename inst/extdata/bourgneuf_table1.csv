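tax_class,taxon_name,code,cluster,n,d13C_mean,d13C_sd,d15N_mean,d15N_sd,ref_tl_mean,ref_tl_se
Actinopterygii,Callionymus lyra,Clyr,BIF,7,-17.4,0.2,12.6,0.6,3.3,0.4
Actinopterygii,Chelidonichthys lucerna,Cluc,SBF,7,-15.7,0.9,15.3,0.3,4,0.1
Actinopterygii,Conger conger,Ccon,DFC,6,-16.8,0.5,15.3,0.7,4.3,0.4
Actinopterygii,Engraulis encrasicolus,Eenc,PSC,7,-18.2,0.2,13,0.6,3.1,0.4
Actinopterygii,Sardina pilchardus,Spil,PSC,6,-18.3,0.6,12.8,0.7,3.1,0.1
Actinopterygii,Sprattus sprattus,Sspr,PSC,7,-19.3,0.3,12,0.5,3,0.1
Actinopterygii,Scomber scombrus,Ssco,PSC,7,-18.5,0.5,12.1,0.8,3.6,0.2
Actinopterygii,Osmerus eperlanus,Oepe,DFC,7,-17.4,0.6,15.5,0.5,3.5,0.4
Actinopterygii,Belone belone,Bbel,BIF,4,-17.4,0.6,13.4,1.5,4.2,0.4
Actinopterygii,Trachurus trachurus,Ttra,DFC,7,-18.1,0.4,15,0.6,3.7,0.0
Actinopterygii,Pollachius pollachius,Ppol,DFC,7,-17.2,1,15.2,0.6,4.3,0.3
Actinopterygii,Trisopterus luscus,Tlus,DFC,7,-16.7,0.7,15.7,0.9,3.7,0.1
Actinopterygii,Merlangius merlangus,Mmerla,DFC,6,-17.5,0.3,16.7,0.6,4.4,0.2
Actinopterygii,Merluccius merluccius,Mmerlu,DFC,7,-18,0.4,14.5,0.7,4.4,0.0
Actinopterygii,Pagrus pagrus,Ppag,DFC,7,-16.6,0.5,15.8,0.5,3.9,0.2
Actinopterygii,Spondyliosoma cantharus,Scant,DFC,7,-17,0.6,15.3,0.5,3.3,0.2
Actinopterygii,Labrus bergylta,Lber,BIF,4,-17.4,1,13.8,0.6,3.2,0.0
Actinopterygii,Solea solea,Ssol,BIF,7,-17.2,1.4,14.1,0.4,3.2,0.2
Chondrichthyes,Raja undulata,Rund,SBF,7,-16,0.6,14.6,0.4,3.5,0.4
Chondrichthyes,Scyliorhinus canicula,Scani,DFC,7,-16.8,0.3,14.6,0.4,3.8,0.3
Cephalopoda,Alloteuthis spp.,Allo,DFC,7,-18.6,0.5,14.6,1.3,3.5,0.4
Cephalopoda,Sepia officinalis,Soff,DFC,7,-17.3,0.2,14.7,0.4,4.3,0.7
Decapoda,Atelecyclus undecimdentatus,Aund,BIF,9,-17.1,0.8,12.5,0.5,2.8,NA
Decapoda,Cancer pagurus,Cpag,BIF,7,-17.3,0.5,13.9,0.7,3.1,NA
Decapoda,Necora puber,Npub,BIF,7,-16.9,0.3,12.9,0.6,2.6,NA
Decapoda,Maja brachydactyla,Mbra,BIF,7,-16.8,0.4,13.3,0.7,3.2,0.2
Decapoda,Pagurus spp.,Pagu,BIF,7,-16.2,0.5,12.9,0.3,3.6,0.2
Decapoda,Crangon spp.,Cran,SBF,7,-15.3,1.2,13.9,0.2,3.2,0.5
Gasteropoda,Buccinum undatum,Bund,BIF,7,-16.4,0.5,13.4,0.7,3.4,0.4
Polychaeta,Aphrodita aculeata,Aacu,BIF,6,-16.6,0.7,13.7,0.7,3.2,0.4
Bivalvia,Pecten maximus,Pmax,BPC,9,-17.9,0.2,10.1,0.4,2,NA
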