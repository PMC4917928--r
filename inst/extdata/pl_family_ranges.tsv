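family	agreement	simui	simgic	mui	mgic	gs2
PL1	0.122	0.298	0.356	0.139	0.147	0.137
PL2	0.391	0.497	0.539	0.214	0.216	0.224
PL3	0.260	0.620	0.825	0.671	0.672	0.238
PL4	0.368	0.376	0.458	0.353	0.343	0.177
PL5	0.874	0.650	0.853	0.801	0.802	0.246
PL6	0.405	0.386	0.429	0.469	0.474	0.175
PL7	0.201	0.432	0.542	0.501	0.505	0.129
PL8	0.180	0.548	0.660	0.329	0.285	0.224
PL9	0.058	0.207	0.270	0.368	0.372	0.080
PL10	0.178	0.368	0.484	0.564	0.559	0.146
PL11	0.229	0.108	0.122	0.378	0.373	0.054
PL12	0.771	0.644	0.838	0.744	0.741	0.247
PL16	0.831	0.613	0.829	0.903	0.905	0.211
PL17	0.869	0.649	0.853	0.831	0.831	0.248
PL22	0.400	0.443	0.521	0.494	0.501	0.191
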