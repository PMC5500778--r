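surface_term,llt_id,llt_label,pt_id,pt_label,soc_label
mal de tête,LLT0001,mal de tête,PT0001,céphalée,affections du système nerveux
mal au crâne,LLT0002,mal au crâne,PT0001,céphalée,affections du système nerveux
céphalée,LLT0003,céphalée,PT0001,céphalée,affections du système nerveux
migraine,LLT0004,migraine,PT0002,migraine,affections du système nerveux
vertige,LLT0005,vertige,PT0003,vertige,affections du système nerveux
somnolence,LLT0006,somnolence,PT0004,somnolence,affections du système nerveux
insomnie,LLT0010,insomnie,PT0010,insomnie,affections psychiatriques
cauchemar,LLT0011,cauchemar,PT0011,cauchemar,affections psychiatriques
anxiété,LLT0012,anxiété,PT0012,anxiété,affections psychiatriques
nausée,LLT0020,nausée,PT0020,nausée,affections gastro-intestinales
vomissement,LLT0021,vomissement,PT0021,vomissement,affections gastro-intestinales
diarrhée,LLT0022,diarrhée,PT0022,diarrhée,affections gastro-intestinales
bouche sèche,LLT0023,bouche sèche,PT0023,sécheresse buccale,affections gastro-intestinales
fatigue,LLT0030,fatigue,PT0030,fatigue,troubles généraux
éruption cutanée,LLT0040,éruption cutanée,PT0040,éruption,affections de la peau
démangeaison,LLT0041,démangeaison,PT0041,prurit,affections de la peau
perte de cheveux,LLT0042,perte de cheveux,PT0042,alopécie,affections de la peau
douleur musculaire,LLT0050,douleur musculaire,PT0050,myalgie,affections musculosquelettiques
crampe,LLT0051,crampe,PT0051,crampe musculaire,affections musculosquelettiques
hypoglycémie,LLT0060,hypoglycémie,PT0060,hypoglycémie,troubles du métabolisme
prise de poids,LLT0061,prise de poids,PT0061,prise de poids,troubles du métabolisme
palpitations,LLT0070,palpitations,PT0070,palpitations,affections cardiaques
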