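breed	n
American Miniature Horse	8
Arabian Horse	19
Ardennes	21
Cold Blooded Trotter	213
Dole Horse	16
French Trotter	56
Gotland Pony	29
Icelandic Horse	185
Kentucky Mountain Horse	23
North Swedish Draft Horse	38
Rocky Mountain Horse	17
Shetland Pony	30
Standardbred	174
Swedish Warmblood	70
Thoroughbred	37
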