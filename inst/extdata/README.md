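# extdata

No data files ship with the package; all test fixtures are generated in
code by the `synth_*` generators.

The Est2 acceptance checks in `tests/testthat/test-acceptance.R` expect
the crystal-structure coordinate file of esterase Est2 (PDB accession
1EVQ) at `1evq.pdb` in this directory (or at the path given by the
`THERMADAPT_1EVQ` environment variable). The file is not redistributed
here; download it from the Protein Data Bank to run those checks.
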