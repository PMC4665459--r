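#dtabayes schema: ordinal
group,category,count
diseased,1,1
diseased,2,0
diseased,3,6
diseased,4,11
diseased,5,12
nondiseased,1,9
nondiseased,2,2
nondiseased,3,11
nondiseased,4,8
nondiseased,5,0
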