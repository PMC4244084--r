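# Human lysozyme, mature chain residues 1-130 (cf. PDB 1REX), 1-letter code.
# Reference sequence bundled for the system-preparation charge arithmetic:
# 130 residues, 14 arginines, net side-chain formal charge +8 e at pH 7.
KVFERCELARTLKRLGMDGYRGISLANWMCLAKWESGYNTRATNYNAGDRSTDYGIFQINSRYWCNDGKTPGAVNACHLSCSALLQDNIADAVACAKRVVRDPQGIRAWVAWRNRCQNRDVRQYVQGCGV
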