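#' Specification of a synthetic labeled PSSM dataset
#'
#' Declares a stated world for testing: classes differ by a shift of their
#' column-mean profiles (`delta`, raw log-odds units, read by the pseudo-PSSM
#' means), by row-to-row AR(1) autocorrelation (`rho_lag`, read by the lag
#' terms) and by a class-specific inter-column correlation pattern
#' (`pair_signal`, read by the detrended cross-correlation coefficients).
#' Defaults state the conditions used for the discrimination checks:
#' 3 classes of 30 proteins, lengths 50-120 (so the default DCCA window
#' S = 40 is always admissible), delta = 6, rho_lag = 0.3, pair_signal = 0.4.
#'
#' @param n_classes number of compartments (>= 1).
#' @param n_per_class proteins per compartment (>= 1).
#' @param length_range integer c(Lmin, Lmax), Lmin >= 2.
#' @param delta inter-class column-mean shift, raw-score units, >= 0.
#' @param rho_lag AR(1) position-to-position correlation in [0, 1).
#' @param pair_signal inter-column correlation strength in [-1, 1].
#' @param seed RNG seed; everything downstream is reproducible from it.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_classes = 3, n_per_class = 30,
                       length_range = c(50, 120), delta = 6, rho_lag = 0.3,
                       pair_signal = 0.4, seed = 1) {
  stopifnot(n_classes >= 1, n_per_class >= 1, length(length_range) == 2,
            length_range[1] >= 2, length_range[1] <= length_range[2],
            delta >= 0, rho_lag >= 0, rho_lag < 1,
            pair_signal >= -1, pair_signal <= 1)
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 delta = delta, rho_lag = rho_lag,
                 pair_signal = pair_signal, seed = as.integer(seed)),
            class = "synth_spec")
}

# deterministic class signatures: a +/-0.5 sign pattern for the mean shift
# and a +/-1 unit pattern for the rank-one column-correlation structure
.class_mean_pattern <- function(cl, n_classes) {
  j <- 0:19
  0.5 * ifelse(((j %/% max(1, cl)) + cl) %% 2 == 0, 1, -1)
}

.class_corr_pattern <- function(cl) {
  j <- 0:19
  ifelse(((j %/% (cl + 1)) %% 2) == 0, 1, -1)
}

#' Generate a labeled synthetic PSSM dataset
#'
#' Per class, rows of the raw profile are drawn as an AR(1)-correlated
#' Gaussian field around the class mean profile, with a rank-one
#' class-specific column covariance scaled by `pair_signal`; scores are
#' rounded to integers and clipped to the typical [-9, 11] range, and each
#' protein's sequence is the per-row argmax residue. Identical spec + seed
#' gives identical output.
#'
#' @param spec a [synth_spec()].
#' @param check_S optional downstream DCCA window parameter; a warning is
#'   raised when `Lmin <= check_S`.
#' @return list with `records` (data.frame id/sequence/label), `pssms`
#'   (list of [raw_pssm()]), `labels` (named integer vector).
#' @export
generate_dataset <- function(spec, check_S = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(check_S) && spec$length_range[1] <= check_S)
    warning("minimum length ", spec$length_range[1],
            " is not larger than the DCCA window parameter S = ", check_S)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  base <- rep(-1, 20)              # typical slightly negative log-odds rows
  noise_sd <- 2.5
  a <- abs(spec$pair_signal)
  n <- spec$n_classes * spec$n_per_class
  ids <- sprintf("SYN%04d", seq_len(n))
  labels <- rep(seq_len(spec$n_classes), each = spec$n_per_class)
  pssms <- vector("list", n)
  seqs <- character(n)
  for (s in seq_len(n)) {
    cl <- labels[s]
    mu <- base + spec$delta * .class_mean_pattern(cl, spec$n_classes)
    v <- .class_corr_pattern(cl) * sign(spec$pair_signal + (a == 0))
    # unit-diagonal covariance (1-a) I + a vv' -> correlated column noise
    Cf <- function(eps) sqrt(1 - a) * eps + sqrt(a) * rnorm(1) * v
    L <- spec$length_range[1] - 1L +
      sample.int(spec$length_range[2] - spec$length_range[1] + 1L, 1L)
    Z <- matrix(0, L, 20)
    z <- Cf(rnorm(20))
    Z[1, ] <- z
    if (L > 1) for (i in 2:L) {
      z <- spec$rho_lag * z + sqrt(1 - spec$rho_lag^2) * Cf(rnorm(20))
      Z[i, ] <- z
    }
    scores <- round(sweep(noise_sd * Z, 2, mu, "+"))
    scores[scores < -9] <- -9L
    scores[scores > 11] <- 11L
    residues <- pssm_residues()[apply(scores, 1, which.max)]
    seqs[s] <- paste0(residues, collapse = "")
    pssms[[s]] <- suppressWarnings(raw_pssm(ids[s], scores, residues))
  }
  list(records = data.frame(id = ids, sequence = seqs, label = labels,
                            stringsAsFactors = FALSE),
       pssms = pssms,
       labels = setNames(as.integer(labels), ids))
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the shapes the pipeline consumes: a FASTA file, a
#' two-column label TSV and one NCBI-dialect PSSM file per protein.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pssm_dir <- file.path(dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  con <- file(file.path(dir, "proteins.fasta"), "w")
  for (i in seq_len(nrow(dataset$records)))
    writeLines(c(paste0(">", dataset$records$id[i]),
                 dataset$records$sequence[i]), con)
  close(con)
  write.table(data.frame(id = dataset$records$id,
                         label = dataset$records$label),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (p in dataset$pssms)
    write_pssm_fixture(p, file.path(pssm_dir, paste0(p$id, ".pssm")))
  invisible(dir)
}
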