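label	diagnosis
TCMR	TCMR
tcmr	TCMR
T cell mediated rejection	TCMR
ABMR	ABMR
abmr	ABMR
antibody mediated rejection	ABMR
MIXED	MIXED
Mixed	MIXED
mixed rejection	MIXED
AKI	AKI
ATN	AKI
acute kidney injury	AKI
delayed graft function	AKI
NR	NOREJECTION
no rejection	NOREJECTION
non-rejecting	NOREJECTION
borderline	NOREJECTION
Normal	NORMAL
normal native	NORMAL
nephrectomy	NORMAL
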