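gene	is_neurogenesis	is_tf	behavior_terms
Nr1d1	TRUE	TRUE	abnormal anxiety-related response
Fmr1	TRUE	TRUE	abnormal aggression-related behavior|increased aggression|abnormal anxiety-related response|abnormal fear-related response|abnormal response to social novelty|abnormal learning/memory/conditioning
Atf2	TRUE	TRUE	abnormal anxiety-related response
Braf	TRUE	FALSE	abnormal aggression-related behavior|increased aggression
Pten	TRUE	FALSE	abnormal aggression-related behavior|abnormal anxiety-related response|abnormal fear-related response
Fxr2	TRUE	TRUE	abnormal fear-related response
Creb1	TRUE	TRUE	
Egr1	TRUE	TRUE	
Htr2c	TRUE	FALSE	
Prlr	TRUE	FALSE	
Epha5	TRUE	FALSE	
Notch3	TRUE	FALSE	
Slc7a11	TRUE	FALSE	
Mif	TRUE	FALSE	
Spred1	FALSE	FALSE	abnormal anxiety-related response
Elavl2	FALSE	TRUE	
Nufip2	FALSE	FALSE	
Sacm1l	FALSE	FALSE	
Xpo1	FALSE	FALSE	
Pcmtd2	FALSE	FALSE	
Hnrnpc	FALSE	FALSE	
9330159F19Rik	FALSE	FALSE	
Tmem33	FALSE	FALSE	
Pcnp	FALSE	FALSE	
Picalm	FALSE	FALSE	
Rexo1	FALSE	FALSE	
Tmem229a	FALSE	FALSE	
Lztfl1	FALSE	FALSE	
Pcm1	FALSE	FALSE	
Abcb7	FALSE	FALSE	
Azin1	FALSE	FALSE	
Rlim	FALSE	FALSE	
Far1	FALSE	FALSE	
Dzip3	FALSE	FALSE	
Eif5a2	FALSE	FALSE	
Pum2	FALSE	FALSE	
Lnp	FALSE	FALSE	
Vcpip1	FALSE	FALSE	
Taok1	FALSE	FALSE	
Fndc3a	FALSE	FALSE	
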