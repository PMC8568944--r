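# internal helpers shared across modules

abort_bad_arg <- function(msg, ...) abort(sprintf(msg, ...), class = "airmorph_error")

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_bad_arg("`%s` must be a single finite number.", name)
  if (strict_min && x <= min)
    abort_bad_arg("`%s` must be > %g (got %g).", name, min, x)
  if (!strict_min && x < min)
    abort_bad_arg("`%s` must be >= %g (got %g).", name, min, x)
  if (x > max) abort_bad_arg("`%s` must be <= %g (got %g).", name, max, x)
  invisible(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing))
    abort_bad_arg("`%s` is missing required column(s): %s.",
                  what, paste(missing, collapse = ", "))
  invisible(data)
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = leave the
# current stream untouched).  Restores .Random.seed afterwards so generators
# never perturb the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_bad_arg("`seed` must be a single integer.")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Vectorised HSV -> RGB (hue, saturation, value in [0,1]); arguments are
# recycled to a common length.
hsv_to_rgb <- function(h, s, v = 1) {
  n <- max(length(h), length(s), length(v))
  h <- rep_len(h, n); s <- rep_len(s, n); v <- rep_len(v, n)
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- g <- b <- numeric(n)
  pick <- function(a0, a1, a2, a3, a4, a5) {
    out <- numeric(n)
    for (k in 0:5) {
      src <- list(a0, a1, a2, a3, a4, a5)[[k + 1]]
      out[i == k] <- src[i == k]
    }
    out
  }
  list(r = pick(v, q, p, p, t, v),
       g = pick(t, v, v, q, p, p),
       b = pick(p, p, t, v, v, q))
}

# Per-pixel HSV saturation of an RGB array (H x W x 3, values in [0,1]).
# S = (max - min) / max, with S = 0 for black pixels.
rgb_saturation <- function(arr) {
  mx <- pmax(arr[, , 1], arr[, , 2], arr[, , 3])
  mn <- pmin(arr[, , 1], arr[, , 2], arr[, , 3])
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  matrix(s, nrow = dim(arr)[1], ncol = dim(arr)[2])
}

shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-connected labeling of a logical matrix. EBImage::bwlabel gives
# 4-connected components; diagonally adjacent 4-labels are merged with a
# union-find over label pairs.
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    nb <- shift_mat(lab, d[1], d[2])
    sel <- lab > 0L & nb > 0L & lab != nb
    if (any(sel)) {
      pairs <- unique(cbind(lab[sel], nb[sel]))
      for (k in seq_len(nrow(pairs))) union2(pairs[k, 1], pairs[k, 2])
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}
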