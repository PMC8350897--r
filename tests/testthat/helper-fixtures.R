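# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from disk except files these helpers write to tempdir().

# A minimal coordinate-sorted SAM file. `pairs` is a data.frame with columns
# name, pos, tlen and optional flag1/flag2, mapq. Returns the file path.
write_test_sam <- function(pairs, path = tempfile(fileext = ".sam")) {
  lines <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:100000")
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    f1 <- if (!is.null(p$flag1)) p$flag1 else 99L
    f2 <- if (!is.null(p$flag2)) p$flag2 else 147L
    mq <- if (!is.null(p$mapq)) p$mapq else 60L
    mpos <- p$pos + p$tlen - 50L
    lines <- c(lines,
      sprintf("%s\t%d\tchr1\t%d\t%d\t50M\t=\t%d\t%d\t*\t*",
              p$name, f1, p$pos, mq, mpos, p$tlen),
      sprintf("%s\t%d\tchr1\t%d\t%d\t50M\t=\t%d\t%d\t*\t*",
              p$name, f2, mpos, mq, p$pos, -p$tlen))
  }
  writeLines(lines, path)
  path
}

# Three proper pairs with template lengths 100, 150, 200 at MAPQ 60.
basic_pairs <- function() {
  data.frame(name = c("r1", "r2", "r3"),
             pos = c(100L, 300L, 600L),
             tlen = c(100L, 150L, 200L))
}

# A degenerate size model: essentially all mass at `at` bp.
point_model <- function(at = 150) {
  build_size_model(w_short = 0, mono_mu = at, mono_sigma = 1e-4)
}

# Small two-class feature matrix with patient structure, for classifier tests.
toy_cohort_fm <- function(master_seed = 42L, n_cancer = 12L, n_control = 12L,
                          fragments = 5000) {
  cohort <- simulate_cohort(cohort_spec(list(
    list(preset = "healthy_urine", n = n_control),
    list(preset = "glioma_urine", n = n_cancer, followups = 2L)),
    fragments_per_sample = fragments, master_seed = master_seed))
  fm <- feature_matrix(cohort$samples, cohort$labels)
  fm
}

# Permute labels at the patient level (all samples of a patient move
# together), preserving class counts.
permute_patient_labels <- function(fmatrix, seed) {
  pts <- unique(fmatrix$patient_id)
  pl <- vapply(pts, function(p)
    fmatrix$label[fmatrix$patient_id == p][1], character(1))
  perm <- gliofrag:::with_seed(seed, sample(pl))
  fmatrix$label <- perm[match(fmatrix$patient_id, pts)]
  fmatrix
}
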