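# Independent brute-force oracles: all-pairs distance matrices plus a
# plain BFS, no cell lists, no igraph. Deliberately naive -- these define
# correctness for the fast implementations.

# Connected components at `cutoff` from the full pairwise distance
# matrix; returns a membership vector.
oracle_components <- function(pos, box, cutoff) {
  n <- nrow(pos)
  if (n == 0) return(integer(0))
  adj <- min_image_dist(pos, pos, box) <= cutoff
  comp <- integer(n); cc <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cc <- cc + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cc
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# Canonical form of a partition: sorted "a,b,c" member strings.
canonical_partition <- function(members) {
  sort(vapply(members, function(m) paste(sort(m), collapse = ","), ""))
}

oracle_partition <- function(pos, box, cutoff, ids = seq_len(nrow(pos))) {
  comp <- oracle_components(pos, box, cutoff)
  canonical_partition(unname(split(ids, comp)))
}

# Brute-force diluted-TG classification from full distance matrices.
oracle_classify <- function(frame, tg_tg = 5.0, tg_pl = 2.8, margin = 2.5) {
  tg <- molecules_of_class(frame, "tg")
  pl <- molecules_of_class(frame, "pl")
  pos <- molecule_positions(frame)
  ids <- as.integer(rownames(pos))
  p_tg <- pos[match(tg, ids), , drop = FALSE]
  p_pl <- pos[match(pl, ids), , drop = FALSE]
  if (!length(tg))
    return(list(lens = integer(0), diluted = integer(0),
                boundary = integer(0), lens_free_pl = pl))
  d_tt <- min_image_dist(p_tg, p_tg, frame$box)
  diag(d_tt) <- Inf
  d_tp <- min_image_dist(p_tg, p_pl, frame$box)
  is_lens <- apply(d_tt, 1, min) <= tg_tg & apply(d_tp, 1, min) > tg_pl
  lens <- tg[is_lens]
  dist_to_lens <- function(p) {
    if (!length(lens)) return(rep(Inf, nrow(p)))
    apply(min_image_dist(p, p_tg[is_lens, , drop = FALSE], frame$box), 1, min)
  }
  free_pl <- pl[dist_to_lens(p_pl) >= margin]
  nonlens <- tg[!is_lens]
  in_free <- dist_to_lens(p_tg[!is_lens, , drop = FALSE]) >= margin
  list(lens = lens, diluted = nonlens[in_free], boundary = nonlens[!in_free],
       lens_free_pl = free_pl)
}

# Random TG-only frame in a periodic box.
random_tg_frame <- function(n, box = c(30, 30, 12)) {
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  bead_frame(pos, box, seq_len(n), rep("TG", n))
}
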