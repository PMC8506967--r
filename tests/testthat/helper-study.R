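# A self-contained synthetic study: complex + one comparison structure
# + one ortholog alignment, written to disk for the pipeline.
make_study <- function(dir, seed = 91) {
  cx <- make_complex(complex_spec(seed = seed))
  # comparison structure: the complex's domain with mild coordinate noise
  dom <- select_residues(cx$structure, selection("A"))
  comp <- cx$structure
  comp$atom <- dom
  comp$water <- comp$water[0, ]
  withr::with_seed(seed + 2, {
    comp$atom$x <- comp$atom$x + stats::rnorm(nrow(comp$atom), 0, 0.1)
    comp$atom$y <- comp$atom$y + stats::rnorm(nrow(comp$atom), 0, 0.1)
    comp$atom$z <- comp$atom$z + stats::rnorm(nrow(comp$atom), 0, 0.1)
  })
  seq_master <- polymer_sequence(dom)$sequence
  gen <- make_msa(msa_spec(n_rows = 100, n_cols = nchar(seq_master),
                           n_invariant = 5, n_conservative = 3,
                           master = seq_master, gap_rate = 0,
                           seed = seed + 3))
  ref_path <- file.path(dir, "reference.pdb")
  cmp_path <- file.path(dir, "comparison.pdb")
  msa_path <- file.path(dir, "orthologs.fasta")
  write_pdb(cx$structure, ref_path)
  write_pdb(comp, cmp_path)
  write_msa(gen$msa, msa_path)
  list(cx = cx, gen = gen,
       config = list(
         reference = list(path = ref_path, bd_chain = "A", pep_chain = "B"),
         comparisons = list(homolog = list(path = cmp_path, chain = "A")),
         msas = list(paralog = list(path = msa_path, ref_id = "ref",
                                    ref_auth_start = 1201L)),
         out_dir = file.path(dir, "out")))
}
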