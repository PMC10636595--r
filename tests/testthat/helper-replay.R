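# Re-apply a recorded training transition stream through the plain-R update
# rules; used to pin the compiled protocol driver to the reference
# implementations.

replay_q <- function(tm, Q0, hp, sarsa = FALSE) {
  Q <- matrix(Q0, 169, 8, byrow = TRUE)   # C++ layout: row-major per cell
  e <- matrix(0, 169, 8)
  pend <- NULL
  for (i in seq_len(nrow(tm))) {
    s <- tm[i, "s"]; a <- tm[i, "a"]; r <- tm[i, "r"]; ns <- tm[i, "ns"]
    blocked <- tm[i, "blocked"] == 1; event <- tm[i, "event"]
    terminal <- event == 1
    if (!sarsa) {
      u <- q_update(Q, e, s, a, r, ns, hp, terminal = terminal, blocked = blocked)
      Q <- u$Q; e <- u$e
    } else {
      if (!is.null(pend)) {
        u <- sarsa_update(Q, e, pend$s, pend$a, pend$r, pend$ns, a, hp,
                          blocked = pend$blocked)
        Q <- u$Q; e <- u$e
      }
      if (terminal) {
        u <- sarsa_update(Q, e, s, a, r, ns, NULL, hp, terminal = TRUE,
                          blocked = blocked)
        Q <- u$Q; e <- u$e
        pend <- NULL
      } else pend <- list(s = s, a = a, r = r, ns = ns, blocked = blocked)
    }
    if (event == 2 && sarsa && !is.null(pend)) {   # truncation flush
      u <- sarsa_update(Q, e, pend$s, pend$a, pend$r, pend$ns, NA, hp,
                        blocked = pend$blocked)
      Q <- u$Q; e <- u$e
      pend <- NULL
    }
    if (event > 0) e[] <- 0
  }
  Q
}

replay_sr <- function(tm, M0, R0, hp) {
  M <- matrix(M0, 169 * 8, 169, byrow = TRUE)
  Rv <- R0
  e <- numeric(169 * 8)
  pend <- NULL
  for (i in seq_len(nrow(tm))) {
    s <- tm[i, "s"]; a <- tm[i, "a"]; r <- tm[i, "r"]; ns <- tm[i, "ns"]
    blocked <- tm[i, "blocked"] == 1; event <- tm[i, "event"]
    terminal <- event == 1
    if (!is.null(pend)) {
      u <- sr_update(M, Rv, e, pend$s, pend$a, pend$ns, pend$r, hp, a2 = a,
                     blocked = pend$blocked)
      M <- u$M; Rv <- u$Rv; e <- u$e
    }
    if (terminal) {
      u <- sr_update(M, Rv, e, s, a, ns, r, hp, terminal = TRUE,
                     blocked = blocked)
      M <- u$M; Rv <- u$Rv; e <- u$e
      pend <- NULL
    } else pend <- list(s = s, a = a, r = r, ns = ns, blocked = blocked)
    if (event == 2) {
      if (!is.null(pend)) {
        u <- sr_update(M, Rv, e, pend$s, pend$a, pend$ns, pend$r, hp, a2 = NULL,
                       blocked = pend$blocked)
        M <- u$M; Rv <- u$Rv; e <- u$e
        pend <- NULL
      }
    }
    if (event > 0) e[] <- 0
  }
  list(M = M, Rv = Rv)
}

replay_tile <- function(tm, hp) {
  w <- matrix(0, 265, 8)
  for (i in seq_len(nrow(tm))) {
    if (tm[i, "event"] == 1) {
      # terminal transition: zero bootstrap
      f <- tile_features(tm[i, "s"])
      delta <- tm[i, "r"] - tile_q_value(w, tm[i, "s"], tm[i, "a"])
      w[f, tm[i, "a"]] <- w[f, tm[i, "a"]] + hp$alpha / length(f) * delta
    } else {
      w <- tile_q_update(w, tm[i, "s"], tm[i, "a"], tm[i, "r"], tm[i, "ns"], hp)
    }
  }
  w
}

replay_mb <- function(tm, map) {
  acts <- action_set()
  g <- graph_model("immediate")
  for (i in seq_len(nrow(tm))) {
    s <- tm[i, "s"]; a <- tm[i, "a"]
    cr <- cell_colrow(s)
    tc <- cr[1, "col"] + acts$dx[a]; tr <- cr[1, "row"] + acts$dy[a]
    if (tc < 0 || tc > 12 || tr < 0 || tr > 12) next
    tgt <- cell_id(tc, tr)
    bonus <- if (!is.na(map$shelter) && tm[i, "ns"] == map$shelter &&
                 s != map$shelter && tm[i, "blocked"] == 0) map$reward else 0
    g <- mb_observe(g, s, tgt, blocked = tm[i, "blocked"] == 1, reward = bonus)
  }
  g
}
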