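%
1	affect
2	positive
3	negative
4	anger
5	anxiety
6	sadness
%
hate*	1	3	4
angr*	1	3	4
furious	1	3	4
rage*	1	3	4
annoy*	1	3	4
mad	1	3	4
fear*	1	3	5
afraid	1	3	5
scar*	1	3	5
terrif*	1	3	5
anxi*	1	3	5
worri*	1	3	5
nervous*	1	3	5
panic*	1	3	5
sad*	1	3	6
unhappy	1	3	6
grie*	1	3	6
miser*	1	3	6
depress*	1	3	6
cry*	1	3	6
happ*	1	2
joy*	1	2
love*	1	2
glad	1	2
delight*	1	2
excit*	1	2
proud	1	2
relie*	1	2
upset*	1	3
guilt*	1	3
numb*	1
surpris*	1
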