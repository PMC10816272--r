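# Hydrogen-bond donor/acceptor perception used for rule-of-five counting.
# hbd: N or O bearing at least one (implicit or explicit) hydrogen.
# hba: every N and O atom (classical rule-of-five convention).
hbd: "[#7!H0,#8!H0]"
hba: "[#7,#8]"
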