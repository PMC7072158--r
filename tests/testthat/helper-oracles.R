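# Brute-force oracles, independent of the package's EBImage-backed
# implementations: direct set arithmetic on pixel coordinates.

oracle_offsets <- function(element) {
  switch(element,
    square = expand.grid(dr = -1:1, dc = -1:1),
    diamond = data.frame(
      dr = c(0, -1, 1, 0, 0),
      dc = c(0, 0, 0, -1, 1)
    )
  )
}

# Erosion: a pixel survives iff every structuring-element offset lands on a
# TRUE pixel (out-of-frame counts as background).
oracle_erode <- function(mask, element) {
  off <- oracle_offsets(element)
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]
    c <- idx[k, 2]
    rr <- r + off$dr
    cc <- c + off$dc
    if (any(rr < 1 | rr > nr | cc < 1 | cc > nc)) next
    out[r, c] <- all(mask[cbind(rr, cc)])
  }
  out
}

# n erosions with the same element sequence the package uses.
oracle_interior <- function(mask, n, element = "octagon") {
  for (i in seq_len(n)) {
    el <- switch(element,
      square = "square",
      diamond = "diamond",
      octagon = if (i %% 2 == 1) "square" else "diamond"
    )
    mask <- oracle_erode(mask, el)
  }
  mask
}

# Flood-fill (4-connected is not enough: match 8-connectivity of bwlabel)
# connected-component labelling by BFS.
oracle_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- r + dr
          cc <- c + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          q <- (cc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Random single-component blob: union of overlapping discs, largest
# component kept via the oracle labeller.
random_blob <- function(size = 48, n_discs = 4, seed = 1) {
  withr::with_seed(seed, {
    mask <- matrix(FALSE, size, size)
    cx <- runif(n_discs, size * 0.35, size * 0.65)
    cy <- runif(n_discs, size * 0.35, size * 0.65)
    rad <- runif(n_discs, size * 0.1, size * 0.22)
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    for (i in seq_len(n_discs)) {
      mask <- mask | ((rows - cx[i])^2 + (cols - cy[i])^2 <= rad[i]^2)
    }
    lab <- oracle_components(mask)
    areas <- tabulate(lab[lab > 0])
    lab == which.max(areas)
  })
}

disc_mask <- function(size, radius) {
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  (rows - ctr)^2 + (cols - ctr)^2 <= radius^2
}
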