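# shared simulations, cached per test run
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, params, t_end = 300, dt = NULL) {
  if (!exists(key, .sim_cache)) {
    assign(key, simulate_clock(params, t_end = t_end, dt = dt), .sim_cache)
  }
  get(key, .sim_cache)
}

wt_sim <- function() cached_sim("wt", clock_params())

wt_summary <- function() {
  if (!exists("wt_sum", .sim_cache))
    assign("wt_sum", summarize_oscillation(wt_sim(), "total_her1"),
           .sim_cache)
  get("wt_sum", .sim_cache)
}

# hand-built constant trajectory for bookkeeping tests
constant_trajectory <- function(state, n = 50) {
  segclock:::new_trajectory(seq(0, by = 0.1, length.out = n),
                            matrix(rep(state, each = n), nrow = n),
                            c("h1", "h6", "h7"),
                            params = clock_params())
}

# independent brute-force H-box oracle: check positions 4-9 of every
# 12-mer window on both strands against the core pattern
brute_force_hbox <- function(seq, strict = FALSE) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  core_ok <- function(core) {
    if (nchar(core) != 6) return(FALSE)
    ok <- substr(core, 1, 4) == "CACG" && substr(core, 6, 6) == "G"
    if (strict) ok <- ok && substr(core, 5, 5) %in% c("T", "C")
    ok
  }
  n <- nchar(seq)
  hits <- list()
  for (p in seq_len(n - 5L)) {         # p = 1-based core start
    hex <- substr(seq, p, p + 5L)
    plus <- core_ok(hex)
    minus <- core_ok(rc(hex)) && !plus # palindrome collapses to +
    for (strand in c("+", "-")[c(plus, minus)]) {
      lo <- p - 3L; hi <- p + 8L
      twelve <- paste0(strrep("N", max(0L, 1L - lo)),
                       substr(seq, max(1L, lo), min(n, hi)),
                       strrep("N", max(0L, hi - n)))
      if (strand == "-") twelve <- rc(twelve)
      hits[[length(hits) + 1L]] <- data.frame(
        start = p - 4L, end = p + 8L, strand = strand,
        twelve_mer = twelve)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(),
                                       end = integer(),
                                       strand = character(),
                                       twelve_mer = character()))
  do.call(rbind, hits)
}
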