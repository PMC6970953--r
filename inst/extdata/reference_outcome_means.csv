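variable,tool,placement,n,summary_kind,center,delta_printed
onset,psg,psg,23,mean,20:37,
onset,actigraph,hip,23,mean,20:44,6
onset,actigraph,wrist,23,mean,20:58,21
offset,psg,psg,23,mean,6:50,
offset,actigraph,hip,23,mean,6:49,0
offset,actigraph,wrist,23,mean,6:45,-5
spt_min,psg,psg,23,mean,613,
spt_min,actigraph,hip,23,mean,606,-7
spt_min,actigraph,wrist,23,mean,586,-27
waso_min,psg,psg,23,median,48,
waso_min,actigraph,hip,23,median,12,-34
waso_min,actigraph,wrist,23,median,48,-7
efficiency_pct,psg,psg,23,median,92.2,
efficiency_pct,actigraph,hip,23,median,98.0,5.8
efficiency_pct,actigraph,wrist,23,median,92.5,1.3
tst_min,psg,psg,23,mean,563,
tst_min,actigraph,hip,23,mean,584,21
tst_min,actigraph,wrist,23,mean,538,-26
onset,actical,hip,23,mean,20:34,-3
onset,actical,wrist,22,mean,20:54,14
offset,actical,hip,23,mean,7:04,14
offset,actical,wrist,22,mean,6:50,-1
spt_min,actical,hip,23,mean,631,18
spt_min,actical,wrist,22,mean,597,-15
waso_min,actical,hip,23,median,0,-45
waso_min,actical,wrist,22,median,17,-24
efficiency_pct,actical,hip,23,median,99.9,7.6
efficiency_pct,actical,wrist,22,median,97.0,4.3
tst_min,actical,hip,23,mean,622,59
tst_min,actical,wrist,22,mean,571,9
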