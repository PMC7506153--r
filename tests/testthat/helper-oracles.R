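# Independent brute-force oracles: per-voxel enumeration, no shared code with
# the vectorised implementations they check.

# Direction steps, duplicated on purpose (the convention is part of the
# contract): angle0 walks columns, angle90 rows, angle45 the (+1,+1)
# diagonals, angle135 the anti-diagonals from their lowest column index.
oracle_step <- function(direction) {
  list(angle0 = c(0L, 1L), angle45 = c(1L, 1L),
       angle90 = c(1L, 0L), angle135 = c(-1L, 1L))[[direction]]
}

glcm_oracle <- function(grey, direction, offset) {
  st <- oracle_step(direction)
  if (direction == "angle135") st <- c(1L, -1L)  # either orientation: symmetrised
  L <- grey$L
  counts <- matrix(0, L, L)
  dims <- dim(grey$levels)
  for (k in seq_len(dims[3])) {
    for (r in seq_len(dims[1])) {
      for (c in seq_len(dims[2])) {
        r2 <- r + st[1] * offset
        c2 <- c + st[2] * offset
        if (r2 < 1 || r2 > dims[1] || c2 < 1 || c2 > dims[2]) next
        a <- grey$levels[r, c, k]
        b <- grey$levels[r2, c2, k]
        if (is.na(a) || is.na(b)) next
        counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
      }
    }
  }
  counts <- counts + t(counts)
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

# Enumerate the scan lines of one slice as lists of (r, c) walks.
oracle_lines <- function(nr, nc, direction) {
  walk <- function(r, c, dr, dc) {
    out <- list()
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      out[[length(out) + 1L]] <- c(r, c)
      r <- r + dr
      c <- c + dc
    }
    out
  }
  switch(direction,
    angle0 = lapply(seq_len(nr), function(r) walk(r, 1L, 0L, 1L)),
    angle90 = lapply(seq_len(nc), function(c) walk(1L, c, 1L, 0L)),
    angle45 = {
      starts <- rbind(cbind(seq_len(nr), 1L), cbind(1L, seq(2L, nc)))
      lapply(seq_len(nrow(starts)), function(i) {
        walk(starts[i, 1], starts[i, 2], 1L, 1L)
      })
    },
    angle135 = {
      # anti-diagonals, walked from their lowest column index (r decreasing)
      starts <- rbind(cbind(seq_len(nr), 1L), cbind(nr, seq(2L, nc)))
      lapply(seq_len(nrow(starts)), function(i) {
        walk(starts[i, 1], starts[i, 2], -1L, 1L)
      })
    }
  )
}

rlm_oracle <- function(grey, direction, step) {
  dims <- dim(grey$levels)
  L <- grey$L
  runs_lv <- integer(0)
  runs_ln <- integer(0)
  n_scanned <- 0L
  for (k in seq_len(dims[3])) {
    for (line in oracle_lines(dims[1], dims[2], direction)) {
      lat <- line[seq(1L, length(line), by = step)]
      cur_lv <- NA_integer_
      cur_len <- 0L
      for (pt in lat) {
        v <- grey$levels[pt[1], pt[2], k]
        if (!is.na(v)) n_scanned <- n_scanned + 1L
        if (!is.na(v) && !is.na(cur_lv) && v == cur_lv) {
          cur_len <- cur_len + 1L
        } else {
          if (cur_len > 0L) {
            runs_lv <- c(runs_lv, cur_lv)
            runs_ln <- c(runs_ln, cur_len)
          }
          cur_lv <- v
          cur_len <- if (is.na(v)) 0L else 1L
        }
      }
      if (cur_len > 0L) {
        runs_lv <- c(runs_lv, cur_lv)
        runs_ln <- c(runs_ln, cur_len)
      }
    }
  }
  if (length(runs_lv) == 0L) return(NULL)
  p <- matrix(0, L, max(runs_ln))
  for (q in seq_along(runs_lv)) {
    p[runs_lv[q] + 1L, runs_ln[q]] <- p[runs_lv[q] + 1L, runs_ln[q]] + 1
  }
  list(p = p, n_runs = length(runs_lv), n_scanned = n_scanned)
}

# AUC by explicit pair counting (Mann-Whitney, half credit for ties).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Random masked grey volume for oracle equivalence checks.
random_grey <- function(dims = c(8, 8, 3), L = 8, p_mask = 0.8) {
  lev <- array(sample(0:(L - 1), prod(dims), replace = TRUE), dims)
  lev[runif(prod(dims)) > p_mask] <- NA_integer_
  if (all(is.na(lev))) lev[1, 1, 1] <- 0L
  grey_volume(lev, L = L)
}

# Digital sphere mask/volume helpers used by several files.
sphere_phantom <- function(radius_mm = 10, dims = c(40, 40, 40), suv_in = 8,
                           suv_out = 1) {
  cx <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) - dims[a] / 2)
  d2 <- outer(outer(cx[[1]]^2, cx[[2]]^2, `+`), cx[[3]]^2, `+`)
  inside <- d2 <= radius_mm^2
  v <- array(suv_out, dims)
  v[inside] <- suv_in
  list(volume = voxel_grid(v), mask = roi_mask(inside), inside = inside)
}
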