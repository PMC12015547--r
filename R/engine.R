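# Internal search engine: per-feature ALTSS-style optimization inside an
# iterative ascent with random restarts, plus a brute-force oracle.
#
# A search state is a named list over codebook features:
#   NULL            - feature unrestricted
#   c(lo, hi)       - ordered feature restricted to encoded bins lo..hi
#   integer vector  - categorical feature restricted to those level indices
# Rows at the missing pseudo-level (0) of a restricted feature are excluded.

empty_state <- function(enc) {
  s <- vector("list", length(enc$features))
  names(s) <- enc$features
  s
}

# Direction-gated ("one-sided") score: subsets on the wrong side of the
# expectation score 0, so the ascent never prefers them and always escapes a
# wrong-side random start.
gated_score <- function(C, B, N, direction) {
  if (N == 0 || !gate_ok(C, B, direction)) 0
  else score_binomial_lr(C, B, N)
}

eval_state <- function(enc, y, mu, state, rho, direction) {
  mask <- state_mask(enc, state)
  N <- sum(mask); C <- sum(y[mask])
  F <- gated_score(C, mu * N, N, direction)
  nl <- state_nl(enc, state)
  list(state = state, mask = mask, C = C, B = mu * N, N = N, F = F,
       NL = nl, F_pen = F - rho * nl)
}

# direction gate: is a (C, B) pair eligible?  The tolerance absorbs floating
# error in B = mu * N (the whole population has C = B only up to rounding).
gate_ok <- function(C, B, direction) {
  eps <- 1e-9 * (1 + abs(B))
  if (direction == "high") C >= B - eps else C <= B + eps
}

# Best restriction of feature `f` given the other features' restrictions.
# Candidates: for ordered features every one-sided bin run (suffix "x >= e",
# prefix "x <= e-"), optionally two-sided intervals; for categorical features
# every prefix of levels ordered by direction-signed observed/expected ratio;
# plus "unrestricted".  Candidates whose (C, B) violate the direction gate are
# ineligible; "unrestricted" always stays available.  Returns the candidate
# maximizing the penalized score of the full description.
optimize_feature <- function(enc, y, mu, state, f, rho, direction,
                             allow_intervals = FALSE) {
  other <- state; other[f] <- list(NULL)
  base <- state_mask(enc, other)
  nl_other <- state_nl(enc, other)
  v <- enc$levels[, f]
  kk <- enc$k[[f]]

  # unrestricted candidate (includes rows missing on f)
  N0 <- sum(base); C0 <- sum(y[base])
  best <- list(sel = NULL, nl = 0L,
               C = C0, N = N0,
               F_pen = gated_score(C0, mu * N0, N0, direction) - rho * nl_other)
  if (N0 == 0L) return(best)          # conditioned subset empty
  if (kk < 2L) return(best)           # constant feature: nothing to restrict

  inb <- base & v > 0L
  cnt <- tabulate(v[inb], nbins = kk)
  pos <- tabulate(v[inb & y], nbins = kk)

  cand_lo <- integer(0); cand_hi <- integer(0); cand_nl <- integer(0)
  cand_sets <- NULL
  if (enc$kind[[f]] == "ordered") {
    ccnt <- cumsum(cnt); cpos <- cumsum(pos)
    lo <- c(2:kk, rep(1L, kk - 1L))
    hi <- c(rep(kk, kk - 1L), 1:(kk - 1L))
    nl <- rep(1L, length(lo))
    if (allow_intervals && kk >= 3L) {
      for (a in 2:(kk - 1L)) { b <- a:(kk - 1L)
        lo <- c(lo, rep(a, length(b))); hi <- c(hi, b)
        nl <- c(nl, rep(2L, length(b)))
      }
    }
    N <- ccnt[hi] - c(0, ccnt)[lo]
    C <- cpos[hi] - c(0, cpos)[lo]
    cand_lo <- lo; cand_hi <- hi; cand_nl <- nl
  } else {
    ratio <- ifelse(cnt > 0, pos / (mu * cnt),
                    if (direction == "high") -Inf else Inf)
    ord <- order(ratio, decreasing = (direction == "high"))
    ccnt <- cumsum(cnt[ord]); cpos <- cumsum(pos[ord])
    len <- seq_len(kk - 1L)                 # proper non-empty prefixes
    N <- ccnt[len]; C <- cpos[len]
    cand_sets <- lapply(len, function(m) sort(ord[seq_len(m)]))
    cand_nl <- rep(1L, length(len))
  }

  B <- mu * N
  eps <- 1e-9 * (1 + abs(B))
  ok <- N > 0 & (if (direction == "high") C >= B - eps else C <= B + eps)
  if (!any(ok)) return(best)
  F <- rep(0, length(N))
  F[ok] <- score_binomial_lr(C[ok], B[ok], N[ok])
  F_pen <- F - rho * (nl_other + cand_nl)

  idx <- which(ok)
  # pick max F_pen, ties: fewer literals, then smaller subset
  o <- idx[order(-F_pen[idx], cand_nl[idx], N[idx])][1L]
  if (F_pen[o] > best$F_pen) {   # unrestricted preferred on exact ties
    best <- list(sel = if (is.null(cand_sets)) c(cand_lo[o], cand_hi[o]) else
                   cand_sets[[o]],
                 nl = cand_nl[o], C = C[o], N = N[o], F_pen = F_pen[o])
  }
  best
}

# One ascent run from a starting state.  Sweeps the free features in the
# given order, re-optimizing one feature at a time conditioned on the rest,
# until a full pass improves the penalized score by no more than `tol`
# (steps that keep the score within tol but drop literals are also taken).
ascent_run <- function(enc, y, mu, rho, direction, start, sweep_order,
                       free, tol, allow_intervals) {
  state <- start
  cur <- eval_state(enc, y, mu, state, rho, direction)
  repeat {
    improved <- FALSE
    for (f in sweep_order) {
      res <- optimize_feature(enc, y, mu, state, f, rho, direction,
                              allow_intervals)
      cand_state <- state; cand_state[f] <- list(res$sel)
      cand <- eval_state(enc, y, mu, cand_state, rho, direction)
      if (cand$F_pen > cur$F_pen + tol ||
          (cand$F_pen > cur$F_pen - tol && cand$NL < cur$NL)) {
        state <- cand_state; cur <- cand; improved <- TRUE
      }
    }
    if (!improved) break
  }
  cur
}

random_start <- function(enc, free, rho) {
  f <- free[sample.int(length(free), 1L)]
  kk <- enc$k[[f]]
  s <- empty_state(enc)
  if (kk >= 2L) {
    if (enc$kind[[f]] == "ordered") {
      if (stats::runif(1) < 0.5) s[[f]] <- c(sample(2:kk, 1L), kk)
      else s[[f]] <- c(1L, sample.int(kk - 1L, 1L))
    } else {
      m <- sample.int(kk - 1L, 1L)
      s[[f]] <- sort(sample.int(kk, m))
    }
  }
  s
}

scan_engine <- function(enc, y, mu, rho, direction = c("high", "low"),
                        restarts = 50L, seed = 1L, tol = 1e-9,
                        forced = NULL, allow_intervals = FALSE) {
  direction <- match.arg(direction)
  if (mu <= 0 || mu >= 1)
    stop("outcome mean is degenerate (", mu, "): nothing to scan")
  free <- enc$features[enc$k >= 2L]
  base_state <- empty_state(enc)
  if (!is.null(forced)) {
    for (f in names(forced)) base_state[f] <- forced[f]
    free <- setdiff(free, names(forced))
  }
  if (length(free) == 0L) stop("no scannable features")
  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    set.seed(substream_seed(seed, paste0("restart", r)))
    start <- if (r == 1L) base_state else {
      s <- random_start(enc, free, rho)
      for (f in names(forced %||% list())) s[f] <- forced[f]
      s
    }
    sweep_order <- sample(free)
    res <- ascent_run(enc, y, mu, rho, direction, start, sweep_order,
                      free, tol, allow_intervals)
    if (is.null(best) || better_result(res, best, enc)) best <- res
  }
  best
}

# tie-break: higher F_pen, fewer literals, smaller subset, lexicographic text
better_result <- function(a, b, enc, codebook = NULL) {
  if (a$F_pen != b$F_pen) return(a$F_pen > b$F_pen)
  if (a$NL != b$NL) return(a$NL < b$NL)
  if (a$N != b$N) return(a$N < b$N)
  sa <- paste(vapply(seq_along(a$state), function(i) paste(names(a$state)[i],
        paste(a$state[[i]], collapse = ",")), ""), collapse = ";")
  sb <- paste(vapply(seq_along(b$state), function(i) paste(names(b$state)[i],
        paste(b$state[[i]], collapse = ",")), ""), collapse = ";")
  sa < sb
}

# Brute-force oracle: enumerate the full candidate description space (every
# combination of per-feature one-sided runs / categorical level subsets /
# unrestricted) and return the global argmax of the penalized score among
# direction-eligible descriptions.  Refuses spaces larger than `max_space`.
exhaustive_engine <- function(enc, y, mu, rho, direction = c("high", "low"),
                              allow_intervals = FALSE, max_space = 1e6) {
  direction <- match.arg(direction)
  if (mu <= 0 || mu >= 1) stop("outcome mean is degenerate")
  feats <- enc$features
  cands <- lapply(feats, function(f) {
    kk <- enc$k[[f]]
    out <- list(NULL)
    if (kk >= 2L) {
      if (enc$kind[[f]] == "ordered") {
        for (a in 2:kk) out <- c(out, list(c(a, kk)))
        for (b in 1:(kk - 1L)) out <- c(out, list(c(1L, b)))
        if (allow_intervals && kk >= 3L)
          for (a in 2:(kk - 1L)) for (b in a:(kk - 1L))
            out <- c(out, list(c(a, b)))
      } else {
        for (m in 1:(kk - 1L))
          out <- c(out, unlist(lapply(
            utils::combn(kk, m, simplify = FALSE), list), recursive = FALSE))
      }
    }
    out
  })
  names(cands) <- feats
  space <- prod(vapply(cands, length, 1))
  if (space > max_space)
    stop("candidate space too large for exhaustive search (~",
         format(space, big.mark = ","), " descriptions)")

  n <- nrow(enc$levels)
  best <- NULL
  state <- empty_state(enc)
  recurse <- function(j, mask) {
    if (j > length(feats)) {
      N <- sum(mask)
      nl <- state_nl(enc, state)
      if (N == 0L && nl > 0L) return()
      C <- sum(y[mask]); B <- mu * N
      if (!gate_ok(C, B, direction)) return()
      F <- if (N > 0) score_binomial_lr(C, B, N) else 0
      res <- list(state = state, C = C, B = B, N = N, F = F, NL = nl,
                  F_pen = F - rho * nl)
      if (is.null(best) || better_result(res, best, enc)) best <<- res
      return()
    }
    f <- feats[j]
    v <- enc$levels[, f]
    for (s in cands[[f]]) {
      state[f] <<- list(s)
      if (is.null(s)) m <- mask
      else if (enc$kind[[f]] == "ordered") m <- mask & v >= s[1L] & v <= s[2L] & v > 0L
      else m <- mask & v %in% s
      recurse(j + 1L, m)
    }
    state[f] <<- list(NULL)
  }
  recurse(1L, rep(TRUE, n))
  best
}
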