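id,phenotype,breed,yield_gb,mapped_pct,ibd_mapped_pct,mean_coverage_x
horse1,MCOA,American Miniature,2.4,95.4,93.1,10901.8
horse2,MCOA,Icelandic Horse,2.8,94.8,91.1,12624.0
horse3,MCOA,Icelandic Horse,2.8,97.8,96.0,13385.2
horse4,MCOA,Rocky Mountain Horse,3.0,96.6,94.5,13522.2
horse5,MCOA,Rocky Mountain Horse,2.4,94.6,92.4,11187.2
horse6,Cyst,American Miniature,2.8,94.1,90.7,12615.1
horse7,Unaffected,American Miniature,2.6,97.0,95.1,11493.6
horse8,Unaffected,American Miniature,2.4,94.9,92.4,11104.2
horse9,Unaffected,Rocky Mountain Horse,2.4,92.4,90.8,10489.8
horse10,Unaffected,Rocky Mountain Horse,12.4,97.9,96.5,57357.6
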