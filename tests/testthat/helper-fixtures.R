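# Shared fixtures: small, code-built scenarios used across test files.

wtParams <- function(...) popModelParams(...)

wtInoculum <- function(cells_per_ml = 1e6, params = popModelParams()) {
  cultureState(s = params@c_total,
               b_ntc = cells_per_ml * params@cell_dw * 1e3)
}

# reduced-volume agent scenario: carrying capacity a few 1e4 cells so event
# counts stay small
agentScenario <- function(n0 = 1e4, volume_ml = 3e-5) {
  list(n0 = n0, volume_ml = volume_ml,
       b0 = n0 * popModelParams()@cell_dw * 1e3 / volume_ml)
}

# independent closed-form pooled t-test oracle (textbook formula)
oracleTTest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tt), na + nb - 2)
}

# brute-force pairwise Tukey decisions via stats::TukeyHSD on aov
oracleTukeyNsd <- function(groups, alpha) {
  labs <- names(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labs, lengths(groups)), levels = labs)
  tk <- stats::TukeyHSD(stats::aov(x ~ g))$g
  k <- length(labs)
  nsd <- matrix(TRUE, k, k, dimnames = list(labs, labs))
  for (r in rownames(tk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    ns <- tk[r, "p adj"] >= alpha
    nsd[pair[1], pair[2]] <- ns
    nsd[pair[2], pair[1]] <- ns
  }
  nsd
}

# does a GroupComparison's letter display agree with a pairwise
# non-significance matrix? (share a letter iff not significantly different)
lettersAgree <- function(gc, nsd) {
  lt <- lettersTable(gc)
  for (i in seq_len(nrow(lt) - 1)) {
    for (j in (i + 1):nrow(lt)) {
      share <- length(intersect(strsplit(lt$letters[i], "")[[1]],
                                strsplit(lt$letters[j], "")[[1]])) > 0
      if (share != nsd[lt$group[i], lt$group[j]]) return(FALSE)
    }
  }
  TRUE
}
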