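# Shared fixtures: everything is generated in code, nothing on disk.

tiny_params <- function(seed = 1L, size = 64L, ...) {
  phantom_params(image_size = size, seed = seed, ...)
}

# a small cache so several test files can share one phantom
fixture_env <- new.env()

fixture_sample <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- generate_sample(tiny_params(seed))
  }
  fixture_env[[key]]
}

# independent scalar-BFS connected-components oracle (package uses a
# vectorised frontier; this one walks pixel by pixel with an explicit queue)
cc_oracle <- function(mask, connectivity = 8) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (c0 in seq_len(W)) {
    for (r0 in seq_len(H)) {
      if (!m[r0, c0] || lab[r0, c0] != 0L) next
      cur <- cur + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (o in offs) {
          rr <- p[1] + o[1]; cc <- p[2] + o[2]
          if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
              m[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue <- c(queue, list(c(rr, cc)))
          }
        }
      }
    }
  }
  lab
}

# canonical form of a labeling: relabel components by their smallest
# column-major pixel index, so two labelings of the same partition agree
canonical_labels <- function(lab) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  firsts <- tapply(seq_along(lab)[lab > 0], lab[lab > 0], min)
  ord <- order(firsts)
  for (k in seq_along(ord)) {
    out[lab == as.integer(names(firsts))[ord[k]]] <- k
  }
  out
}

# exhaustive O(N * M) Euclidean distance oracle
dt_oracle <- function(source) {
  H <- nrow(source); W <- ncol(source)
  idx <- which(source != 0)
  sr <- (idx - 1) %% H + 1
  sc <- (idx - 1) %/% H + 1
  out <- matrix(0, H, W)
  for (c0 in seq_len(W)) {
    for (r0 in seq_len(H)) {
      out[r0, c0] <- sqrt(min((sr - r0)^2 + (sc - c0)^2))
    }
  }
  out
}

random_mask <- function(H, W, p = 0.3) {
  matrix(stats::runif(H * W) < p, H, W)
}
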