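#' Generate synthetic binding titration series
#'
#' Emulates microfluidic equilibrium binding titrations in the linear
#' (sub-Kd) regime: free-signal values are log-spaced over the given range
#' and the bound signal follows `background + slope_true * free *
#' exp(eps)` with `eps ~ Normal(0, noise_cv)` (multiplicative log-normal
#' noise keeps signals positive and CV-scaled). The true slopes are
#' proportional to 1/Kd, so slope ratios of fits recover relative
#' affinities.
#'
#' @param truth Named numeric vector mapping probe id to true relative
#'   1/Kd (the true slope).
#' @param n_points Titration points per probe (>= 3; default 8).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.1).
#' @param seed Integer seed; identical configurations produce identical
#'   output.
#' @param free_range Range of free-signal values (arbitrary units),
#'   log-spaced.
#' @param background Constant background fluorescence added to the bound
#'   signal.
#' @param group Library tag stored on each series.
#' @return Named list of [binding_series()], with the ground truth attached
#'   as attribute `truth`.
#' @examples
#' set <- gen_binding_series(c(strong = 1, weak = 0.25), noise_cv = 0,
#'                           seed = 1)
#' fit_relative_affinity(set$strong)$slope # exactly 1
#' @export
gen_binding_series <- function(truth, n_points = 8, noise_cv = 0.1,
                               seed = 0, free_range = c(1, 100),
                               background = 0.5, group = NA_character_) {
  stopifnot(is.numeric(truth), !is.null(names(truth)), n_points >= 3)
  with_seed(seed, {
    free <- exp(seq(log(free_range[1]), log(free_range[2]),
                    length.out = n_points))
    out <- lapply(names(truth), function(id) {
      eps <- if (noise_cv > 0) stats::rnorm(n_points, 0, noise_cv)
             else numeric(n_points)
      bound <- background + truth[[id]] * free * exp(eps)
      binding_series(id, free, bound, group = group)
    })
    names(out) <- names(truth)
    attr(out, "truth") <- truth
    out
  })
}

#' Generate a synthetic somite-boundary table
#'
#' Boundary-formation times are linear in somite index with Gaussian timing
#' noise: `time = onset + true_period * (somite_index - first) +
#' Normal(0, timing_sd)`, with per-embryo onsets jittered uniformly.
#' Genotype-specific true periods encode the effect sizes under study
#' (e.g. hes6 heterozygotes 2% and homozygotes 6% slower than wildtype).
#'
#' @param true_period Named numeric vector: genotype -> true period in
#'   minutes per somite.
#' @param n_embryos Embryos per genotype (scalar or named vector).
#' @param somite_range Contiguous somite indices annotated per embryo
#'   (default 2:17).
#' @param timing_sd Standard deviation of the boundary timing noise in
#'   minutes.
#' @param seed Integer seed.
#' @param n_batches Number of experimental batches embryos are spread over
#'   (round-robin; default 1).
#' @param onset_jitter Half-width of the uniform per-embryo onset jitter in
#'   minutes.
#' @return Data.frame with columns `embryo_id`, `batch`, `genotype`,
#'   `somite_index`, `time_min`; ground truth attached as attribute
#'   `truth`.
#' @examples
#' b <- gen_boundary_table(c(wildtype = 24, hes6 = 24 * 1.06),
#'                         n_embryos = 5, timing_sd = 0, seed = 1)
#' @export
gen_boundary_table <- function(true_period, n_embryos = 25,
                               somite_range = 2:17, timing_sd = 0.72,
                               seed = 0, n_batches = 1, onset_jitter = 10) {
  stopifnot(is.numeric(true_period), !is.null(names(true_period)),
            length(somite_range) >= 3)
  if (length(n_embryos) == 1L)
    n_embryos <- stats::setNames(rep(n_embryos, length(true_period)),
                                 names(true_period))
  with_seed(seed, {
    rows <- list()
    for (g in names(true_period)) {
      ng <- n_embryos[[g]]
      if (ng == 0) next
      for (e in seq_len(ng)) {
        onset <- stats::runif(1, 0, onset_jitter)
        noise <- if (timing_sd > 0)
          stats::rnorm(length(somite_range), 0, timing_sd)
        else numeric(length(somite_range))
        tm <- onset + true_period[[g]] *
          (somite_range - somite_range[1]) + noise
        rows[[length(rows) + 1L]] <- data.frame(
          embryo_id = sprintf("%s_%02d", g, e),
          batch = sprintf("batch%d", 1L + (e - 1L) %% n_batches),
          genotype = g, somite_index = somite_range, time_min = tm)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- true_period
    out
  })
}

#' Generate a synthetic promoter sequence with planted H-boxes
#'
#' Random i.i.d. background DNA at the given GC content with known 12-mers
#' spliced in at fixed positions; the planted loci are returned as a
#' BED-style truth table for closed-loop recovery tests of the scanner.
#'
#' @param length Sequence length in nt.
#' @param planted List of `list(pos, twelve_mer)` entries (or a data.frame
#'   with columns `pos`, `twelve_mer`); `pos` is the 0-based start of the
#'   12-mer. Planted motifs must fit and must not overlap.
#' @param gc Background GC fraction (default 0.4).
#' @param seed Integer seed.
#' @param avoid_spurious If `TRUE`, background positions that happen to
#'   spell an H-box core on either strand are re-drawn, so the planted
#'   sites are the only hits (the single-site promoter-scan scenario).
#' @param name Contig name.
#' @return List with `seq` (named character), `truth` (data.frame
#'   `contig`, `start`, `end`, `twelve_mer`).
#' @export
gen_promoter <- function(length = 5000, planted = list(), gc = 0.4,
                         seed = 0, avoid_spurious = FALSE,
                         name = "promoter") {
  if (is.data.frame(planted))
    planted <- lapply(seq_len(nrow(planted)), function(i)
      list(pos = planted$pos[i], twelve_mer = planted$twelve_mer[i]))
  pos <- vapply(planted, function(p) as.integer(p$pos), integer(1))
  mer <- vapply(planted, function(p) toupper(p$twelve_mer), character(1))
  if (any(nchar(mer) != 12L)) stop("planted motifs must be 12-mers")
  if (any(pos < 0) || any(pos + 12L > length))
    stop("planted motifs must lie within the sequence")
  if (length(pos) > 1L) {
    o <- order(pos)
    if (any(diff(pos[o]) < 12L)) stop("planted motifs must not overlap")
  }
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    draw <- function(n) sample(names(probs), n, replace = TRUE,
                               prob = probs)
    ch <- draw(length)
    plant <- function() {
      for (i in seq_along(pos))
        ch[(pos[i] + 1L):(pos[i] + 12L)] <<- strsplit(mer[i], "")[[1]]
    }
    plant()
    if (avoid_spurious && length >= 12L) {
      footprint <- unlist(lapply(pos, function(p) (p + 1L):(p + 12L)))
      repeat {
        hits <- scan_hbox_core_positions(paste(ch, collapse = ""))
        spurious <- hits[vapply(hits, function(h)
          !any((h:(h + 5L)) %in% footprint), logical(1))]
        if (!length(spurious)) break
        for (h in spurious) ch[h:(h + 5L)] <- draw(6L)
        plant()
      }
    }
    s <- paste(ch, collapse = "")
    truth <- data.frame(contig = rep(name, length(pos)), start = pos,
                        end = pos + 12L, twelve_mer = mer)
    list(seq = stats::setNames(s, name), truth = truth)
  })
}

# 1-based core start positions of H-box matches on either strand
scan_hbox_core_positions <- function(seq) {
  h <- scan_hbox(stats::setNames(seq, "s"))
  if (!nrow(h)) return(integer())
  sort(unique(h$start + 3L + 1L))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}
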