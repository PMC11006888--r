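# Synthetic transmembrane-domain table for a CP47-like 508-residue
# protein: six TMDs with a 192-residue lumenal loop between TMD V and
# TMD VI.  Interval scale mimics the described topology; coordinates are
# NOT measured values.
tmd_label	start_residue	end_residue
TMD I	30	52
TMD II	65	87
TMD III	120	142
TMD IV	155	177
TMD V	210	232
TMD VI	425	447
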