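#' Scan DNA sequence for H-box sites
#'
#' The H-box is the shared consensus binding site of the Hes/Her repressor
#' dimers: the hexamer `CACGNG` (the in-vivo-relevant subset `CACG[T/C]G`
#' is available via `strict = TRUE`). Both strands are scanned; every core
#' match is reported as a 12-mer with `flank` nucleotides of context on
#' each side (hits closer than `flank` to a sequence end are padded with
#' `N`). The palindromic core `CACGTG` matches both strands at the same
#' locus and is collapsed to a single hit on the + strand. `N` bases in the
#' input never match the core.
#'
#' @param x Sequence input: a (optionally named) character vector of DNA
#'   strings, a `Biostrings::DNAString`/`DNAStringSet`, or a path to a
#'   FASTA file.
#' @param flank Flank length around the 6-mer core (default 3, giving
#'   12-mers).
#' @param strict Restrict the degenerate position to T or C.
#' @return A data.frame of hits with columns `contig`, `start`, `end`
#'   (0-based half-open coordinates of the 12-mer on the + strand),
#'   `strand`, `twelve_mer` (strand-oriented, so its positions 4-9 always
#'   spell the core), `core`.
#' @examples
#' scan_hbox("ACTCACGTGAGA") # the single hes6-upstream H-box 12-mer
#' @export
scan_hbox <- function(x, flank = 3, strict = FALSE) {
  seqs <- as_dna_character(x)
  out <- lapply(seq_along(seqs), function(i)
    scan_hbox_one(seqs[[i]], names(seqs)[i], flank, strict))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      twelve_mer = character(), core = character())
  res
}

as_dna_character <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    seqs <- as.character(x)
  } else if (inherits(x, "DNAString")) {
    seqs <- stats::setNames(as.character(x), "seq1")
  } else if (is.character(x) && length(x) == 1L &&
             !grepl("^[ACGTNacgtn]+$", x) && file.exists(x)) {
    seqs <- as.character(Biostrings::readDNAStringSet(x))
  } else if (is.character(x)) {
    seqs <- toupper(x)
    if (is.null(names(seqs)))
      names(seqs) <- paste0("seq", seq_along(seqs))
  } else stop("unsupported sequence input")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence(s) contain characters outside {A,C,G,T,N}: ",
         paste(names(seqs)[bad], collapse = ", "))
  as.list(seqs)
}

scan_hbox_one <- function(seq, contig, flank, strict) {
  flank <- as.integer(flank)
  n <- nchar(seq)
  if (n < 12L) stop("sequence '", contig, "' is shorter than 12 nt")
  ch <- strsplit(seq, "")[[1]]
  idx <- seq_len(n - 5L)
  s <- function(k) ch[idx + k - 1L]
  anyb <- function(v) v %in% c("A", "C", "G", "T")
  plus <- s(1) == "C" & s(2) == "A" & s(3) == "C" & s(4) == "G" &
    (if (strict) s(5) %in% c("T", "C") else anyb(s(5))) & s(6) == "G"
  minus <- s(1) == "C" &
    (if (strict) s(2) %in% c("A", "G") else anyb(s(2))) &
    s(3) == "C" & s(4) == "G" & s(5) == "T" & s(6) == "G"
  # palindromic CACGTG: drop the duplicate minus-strand hit
  minus <- minus & !plus
  mk_hits <- function(pos, strand) {
    if (!length(pos)) return(NULL)
    start0 <- pos - 1L - flank   # 0-based start of the flanked site
    end0 <- start0 + 2L * flank + 6L
    twelve <- vapply(pos, function(p) {
      lo <- p - flank; hi <- p + 5L + flank
      pad_l <- max(0L, 1L - lo); pad_r <- max(0L, hi - n)
      core12 <- substr(seq, max(1L, lo), min(n, hi))
      paste0(strrep("N", pad_l), core12, strrep("N", pad_r))
    }, character(1))
    if (strand == "-") twelve <- revcomp(twelve)
    data.frame(contig = contig, start = start0, end = end0,
               strand = strand, twelve_mer = twelve,
               core = substr(twelve, flank + 1L, flank + 6L))
  }
  rbind(mk_hits(which(plus), "+"), mk_hits(which(minus), "-"))
}

revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "")[[1]])
    paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch],
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write H-box hits as BED6
#'
#' Columns: contig, start, end, name (the 12-mer), score (normalized
#' affinity x 1000 when supplied, else 0), strand.
#'
#' @param hits Data.frame from [scan_hbox()].
#' @param path Output file.
#' @param normalized Optional numeric vector of normalized affinities
#'   aligned with `hits` rows.
#' @return `path`, invisibly.
#' @export
write_hbox_bed <- function(hits, path, normalized = NULL) {
  score <- if (is.null(normalized)) rep(0L, nrow(hits))
           else as.integer(round(1000 * normalized))
  bed <- data.frame(hits$contig, hits$start, hits$end, hits$twelve_mer,
                    score, hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
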