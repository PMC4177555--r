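class,1,2,3,4,5,6,7,8,9,10
BMC Bioinformatics,34,1,3,0,2,0,0,0,0,0
BMC Evo Biol,9,16,3,0,5,0,6,1,0,0
BMC Genomics,7,12,7,0,9,0,1,0,4,0
BMC Neuroscience,3,0,1,15,11,0,5,0,5,0
BMC Cancer,0,0,0,8,21,6,0,5,0,0
BMC Public Health,0,0,0,0,2,31,6,1,0,0
Malaria J,0,1,2,1,2,8,25,0,1,0
J Cardiovas Magn R,0,0,0,0,0,1,1,38,0,0
Retrovirology,0,1,0,1,2,6,0,0,30,0
J Med Case Rep,0,0,0,0,16,1,0,6,3,14
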