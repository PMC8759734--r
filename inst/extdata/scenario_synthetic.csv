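"id","study","exercise_type","cost_eur","pain_net_change_pct","function_net_change_pct","supervised_sessions","period_weeks","n_exercise","n_control"
"cheung-yoga","Cheung-like arm (synthetic)","yoga",550,16,17,8,10,18,18
"krasilshchikov-mixed","Krasilshchikov-like arm (synthetic)","resistance+aerobic",480,22,38,24,12,20,19
"braghin-strength","Braghin-like arm (synthetic)","resistance",320,18,22,20,16,25,24
"lin-taichi","Lin-like arm (synthetic)","tai-chi",450,16,30,26,24,32,31
"home-program","Home programme arm (synthetic)","home-program",0,8,6,0,12,24,25
"intensive-individual","Intensive supervised arm (synthetic)","resistance",1500,28,45,36,26,15,14
"aquatic-group","Aquatic group arm (synthetic)","aquatic",700,12,20,18,20,27,26
"longterm-light","Long light programme arm (synthetic)","aerobic",250,20,18,10,52,30,29
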