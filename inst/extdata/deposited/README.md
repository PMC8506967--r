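# Deposited coordinate files (not distributed)

Checks against the published crystal structures need the deposited
coordinate files, which are not redistributed with this package.  To
enable them, place PDB-format files here:

- `7LHY.pdb` — CeSMARCA4 bromodomain–H3K14ac complex (reference)
- `2GRC.pdb` — HsSMARCA4 apo bromodomain
- `BAZ2B_complex.pdb` — BAZ2B bromodomain–H3K14ac complex
- `ASH1L.pdb` — ASH1L bromodomain

Every other test and the acceptance script run entirely on synthetic
data generated in code.
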