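name,system,pattern,surface_forms,case_fixed
anti-D,Rh,(?i)anti[- ]?d,D,FALSE
anti-C,Rh,(?i:anti[- ]?)C,C,TRUE
anti-c,Rh,(?i:anti[- ]?)c,c,TRUE
anti-E,Rh,(?i:anti[- ]?)E,E,TRUE
anti-e,Rh,(?i:anti[- ]?)e,e,TRUE
anti-Cw,Rh,(?i:anti[- ]?)C(?i:[- ]?\(?w\)?),Cw|C(w)|C w,TRUE
anti-Cx,Rh,(?i:anti[- ]?)C(?i:[- ]?\(?x\)?),Cx|C(x),TRUE
anti-G,Rh,(?i)anti[- ]?g,G,FALSE
anti-f,Rh,(?i)anti[- ]?f,f,FALSE
anti-K,Kell,(?i:anti[- ]?)K(?i:ell)?,K|Kell,TRUE
anti-k,Kell,(?i:anti[- ]?)k(?i:[- ]?\(?cellano\)?)?,k|k (cellano),TRUE
anti-Kpa,Kell,(?i)anti[- ]?kp[- ]?\(?a\)?,Kpa|Kp(a),FALSE
anti-Kpb,Kell,(?i)anti[- ]?kp[- ]?\(?b\)?,Kpb|Kp(b),FALSE
anti-Jsa,Kell,(?i)anti[- ]?js[- ]?\(?a\)?,Jsa|Js(a),FALSE
anti-Jsb,Kell,(?i)anti[- ]?js[- ]?\(?b\)?,Jsb|Js(b),FALSE
anti-Ku,Kell,(?i)anti[- ]?ku,Ku,FALSE
anti-Fya,Duffy,(?i)anti[- ]?fy[- ]?\(?a\)?,Fya|Fy(a)|Fy a,FALSE
anti-Fyb,Duffy,(?i)anti[- ]?fy[- ]?\(?b\)?,Fyb|Fy(b),FALSE
anti-Fy3,Duffy,(?i)anti[- ]?fy[- ]?3,Fy3,FALSE
anti-Jka,Kidd,(?i)anti[- ]?jk[- ]?\(?a\)?,Jka|Jk(a),FALSE
anti-Jkb,Kidd,(?i)anti[- ]?jk[- ]?\(?b\)?,Jkb|Jk(b),FALSE
anti-Jk3,Kidd,(?i)anti[- ]?jk[- ]?3,Jk3,FALSE
anti-M,MNS,(?i)anti[- ]?m,M,FALSE
anti-N,MNS,(?i)anti[- ]?n,N,FALSE
anti-S,MNS,(?i:anti[- ]?)S,S,TRUE
anti-s,MNS,(?i:anti[- ]?)s,s,TRUE
anti-U,MNS,(?i)anti[- ]?u,U,FALSE
anti-Mia,MNS,(?i)anti[- ]?mi[- ]?\(?a\)?,Mia|Mi(a),FALSE
anti-Vw,MNS,(?i)anti[- ]?vw,Vw,FALSE
anti-Mur,MNS,(?i)anti[- ]?mur,Mur,FALSE
anti-Lea,Lewis,(?i)anti[- ]?le[- ]?\(?a\)?,Lea|Le(a)|Le a,FALSE
anti-Leb,Lewis,(?i)anti[- ]?le[- ]?\(?b\)?,Leb|Le(b),FALSE
anti-Leab,Lewis,(?i)anti[- ]?le[- ]?\(?ab\)?,Leab|Le(ab),FALSE
anti-Lua,Lutheran,(?i)anti[- ]?lu[- ]?\(?a\)?,Lua|Lu(a),FALSE
anti-Lub,Lutheran,(?i)anti[- ]?lu[- ]?\(?b\)?,Lub|Lu(b),FALSE
anti-P1,P,(?i)anti[- ]?p[- ]?1,P1|P 1,FALSE
anti-PP1Pk,P,(?i)anti[- ]?pp1pk,PP1Pk,FALSE
anti-A1,Other,(?i)anti[- ]?a[- ]?1,A1|A 1,FALSE
anti-Bg,Other,(?i)anti[- ]?bg(?:[- ]?\(?a\)?)?,Bg|Bg(a)|Bga,FALSE
anti-H,Other,(?i)anti[- ]?h,H,FALSE
anti-HI,Other,(?i)anti[- ]?hi,HI,FALSE
anti-I,Other,(?i:anti[- ]?)I,I,TRUE
anti-i,Other,(?i:anti[- ]?)i,i,TRUE
anti-Wra,Other,(?i)anti[- ]?wr[- ]?\(?a\)?,Wra|Wr(a),FALSE
anti-Wrb,Other,(?i)anti[- ]?wr[- ]?\(?b\)?,Wrb|Wr(b),FALSE
anti-Dia,Other,(?i)anti[- ]?di[- ]?\(?a\)?,Dia|Di(a),FALSE
anti-Dib,Other,(?i)anti[- ]?di[- ]?\(?b\)?,Dib|Di(b),FALSE
anti-Doa,Other,(?i)anti[- ]?do[- ]?\(?a\)?,Doa|Do(a),FALSE
anti-Dob,Other,(?i)anti[- ]?do[- ]?\(?b\)?,Dob|Do(b),FALSE
anti-Coa,Other,(?i)anti[- ]?co[- ]?\(?a\)?,Coa|Co(a),FALSE
anti-Cob,Other,(?i)anti[- ]?co[- ]?\(?b\)?,Cob|Co(b),FALSE
anti-Yta,Other,(?i)anti[- ]?yt[- ]?\(?a\)?,Yta|Yt(a),FALSE
anti-Ytb,Other,(?i)anti[- ]?yt[- ]?\(?b\)?,Ytb|Yt(b),FALSE
anti-Xga,Other,(?i)anti[- ]?xg[- ]?\(?a\)?,Xga|Xg(a),FALSE
anti-Sc1,Other,(?i)anti[- ]?sc[- ]?1,Sc1,FALSE
anti-Vel,Other,(?i)anti[- ]?vel,Vel,FALSE
anti-Lan,Other,(?i)anti[- ]?lan,Lan,FALSE
anti-Jra,Other,(?i)anti[- ]?jr[- ]?\(?a\)?,Jra|Jr(a),FALSE
anti-Ge,Other,(?i)anti[- ]?ge(?:rbich)?,Ge|Gerbich,FALSE
anti-Ch,Other,(?i)anti[- ]?ch(?:ido)?,Ch|Chido,FALSE
anti-Rg,Other,(?i)anti[- ]?rg,Rg,FALSE
anti-Kna,Other,(?i)anti[- ]?kn[- ]?\(?a\)?,Kna|Kn(a),FALSE
anti-McCa,Other,(?i)anti[- ]?mcc[- ]?\(?a\)?,McCa|McC(a),FALSE
anti-Sda,Other,(?i)anti[- ]?sd[- ]?\(?a\)?,Sda|Sd(a),FALSE
unspecified,Other,(?i)(?:ospecificerade|ospecificerad|ospecifika|ospecifik|ospec|unspecified),ospecificerade antikroppar|ospec ak|unspecified antibodies,FALSE
profylax,prophylaxis,(?i)profylax,Rh-profylax given|efter Rh-profylax|anti-D profylax,FALSE
prophylaxis_en,prophylaxis,(?i)prophylax,RhD prophylaxis administered|anti-D after prophylaxis,FALSE
immunglobulin,prophylaxis,(?i)immun[o]?globulin,anti-D immunglobulin givet|anti-D immunoglobulin given,FALSE
rhesonativ,prophylaxis,(?i)rhesonativ,RhesoNativ givet,FALSE
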