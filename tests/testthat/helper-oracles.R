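## Independent reference implementation of the greedy loop, written
## directly from the procedure's definition: score-all, emit top,
## delete its peaks, rescore, drop under-matched, repeat.
referenceGreedy <- function(peaks, psms, tol = 20, min_matched = 4L,
                            max_emit = 5L, mz_range = c(100, 2000)) {
  frag <- lapply(seq_len(nrow(psms)), function(i) {
    f <- generateFragments(psms$sequence[i], psms$mods[i])
    f[f$mz >= mz_range[1] & f$mz <= mz_range[2], ]
  })
  scoreOne <- function(f, pkm) {
    if (!nrow(pkm)) return(list(score = 0, n = 0L, peaks = integer(0),
                                nb = 0L, ny = 0L))
    hits <- integer(0); isb <- logical(0)
    for (r in seq_len(nrow(f))) {
      d <- abs(pkm[, 1] - f$mz[r])
      ok <- which(d <= f$mz[r] * tol * 1e-6)
      if (length(ok)) {
        best <- ok[order(d[ok], pkm[ok, 1])][1]
        hits <- c(hits, best); isb <- c(isb, f$series[r] == "b")
      }
    }
    nb <- sum(isb); ny <- sum(!isb)
    sb <- sum(pkm[hits[isb], 2]); sy <- sum(pkm[hits[!isb], 2])
    sc <- if (nb + ny == 0) 0 else
      lgamma(min(nb, 64) + 1) / log(10) + lgamma(min(ny, 64) + 1) / log(10) +
      log10(max(sb, 1)) + log10(max(sy, 1))
    list(score = sc, n = nb + ny, peaks = unique(hits), nb = nb, ny = ny)
  }
  alive <- seq_len(nrow(psms))
  pkm <- peaks
  origmap <- seq_len(nrow(peaks))
  emitted <- data.frame(idx = integer(0), score = numeric(0))
  while (length(alive) && nrow(emitted) < max_emit) {
    st <- lapply(frag[alive], scoreOne, pkm = pkm)
    sc <- vapply(st, `[[`, numeric(1), "score")
    nm <- vapply(st, function(s) s$n, integer(1))
    ord <- order(-sc, -nm, psms$sequence[alive], psms$assumed_charge[alive])
    top <- ord[1]
    emitted <- rbind(emitted, data.frame(idx = alive[top], score = sc[top]))
    claimed <- st[[top]]$peaks
    if (length(claimed)) {
      keep <- setdiff(seq_len(nrow(pkm)), claimed)
      pkm <- pkm[keep, , drop = FALSE]
      origmap <- origmap[keep]
    }
    alive <- alive[-top]
    if (!length(alive)) break
    st2 <- lapply(frag[alive], scoreOne, pkm = pkm)
    alive <- alive[vapply(st2, function(s) s$n, integer(1)) >= min_matched]
  }
  emitted
}
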