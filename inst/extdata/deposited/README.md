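# Deposited inputs for the reproduction tests

The reproduction tests in `test-acceptance.R` recompute published
comparative numbers from deposited coordinates and reference sequences.
Those inputs are not redistributed with the package; place them in this
directory (or in `inst/extdata/deposited/` before installation) to run the
reproductions:

- `6K0G.pdb`, `6K0H.pdb`, `6K0I.pdb` — the B. longum GalE ternary complexes
  (UDP, UDP-GlcNAc and UDP-Glc, respectively), e.g. from
  `https://files.rcsb.org/download/<ID>.pdb`.
- `1HZJ.pdb` — human GalE; chain B is used.
- `1SB8.pdb` — P. aeruginosa WbpP.
- `6K0G_dimer.pdb` — the biological dimer of 6K0G as a two-chain file
  (generate the crystallographic 2-fold mate with any symmetry-expansion
  tool and keep exactly two protein chains).
- `sequences.fasta` — protein sequences with ids `bGalE`, `hGalE`,
  `BLLJ_1592`, `GalE_3ENK` (the Burkholderia pseudomallei template,
  PDB 3ENK) and `bGalE_construct` (the 348-residue recombinant construct:
  residues 1-340 plus the C-terminal His6 tag).

Without these files the reproduction tests fail with a message naming the
missing input; all synthetic desk-scale tests are unaffected.
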