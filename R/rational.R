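# Arbitrary-precision integers and exact rationals.
#
# Integers are stored as sign + little-endian limb vectors in base 1e6 so that
# every intermediate product (limb * limb, plus convolution carries) stays well
# inside the 2^53 exact-integer range of a double. Rationals are reduced to
# lowest terms with a positive denominator after every operation, matching the
# form in which the worked examples print their coefficients.

BI_BASE <- 1e6

## ---- big integers ----------------------------------------------------------

bi_norm <- function(d, s) {
  if (length(d)) {
    carry <- 0
    for (i in seq_along(d)) {
      v <- d[i] + carry
      carry <- floor(v / BI_BASE)
      d[i] <- v - carry * BI_BASE
    }
    while (carry > 0) {
      d <- c(d, carry %% BI_BASE)
      carry <- floor(carry / BI_BASE)
    }
    while (length(d) && d[length(d)] == 0) d <- d[-length(d)]
  }
  if (!length(d)) return(list(s = 0L, d = numeric(0)))
  list(s = as.integer(s), d = d)
}

bi <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), x == trunc(x))
  if (abs(x) >= 2^53) stop("integer literal too large for exact conversion")
  s <- if (x > 0) 1L else if (x < 0) -1L else 0L
  x <- abs(x)
  d <- numeric(0)
  while (x > 0) {
    d <- c(d, x %% BI_BASE)
    x <- floor(x / BI_BASE)
  }
  list(s = s, d = d)
}

bi_zero <- function() list(s = 0L, d = numeric(0))
bi_is_zero <- function(a) a$s == 0L

bi_cmp_abs <- function(a, b) {
  na <- length(a$d); nb <- length(b$d)
  if (na != nb) return(if (na > nb) 1L else -1L)
  if (na == 0L) return(0L)
  for (i in na:1) {
    if (a$d[i] != b$d[i]) return(if (a$d[i] > b$d[i]) 1L else -1L)
  }
  0L
}

bi_add_abs <- function(a, b) {
  n <- max(length(a$d), length(b$d))
  da <- c(a$d, numeric(n - length(a$d)))
  db <- c(b$d, numeric(n - length(b$d)))
  da + db
}

bi_sub_abs <- function(a, b) { # |a| >= |b|
  n <- length(a$d)
  da <- a$d
  db <- c(b$d, numeric(n - length(b$d)))
  d <- da - db
  borrow <- 0
  for (i in seq_len(n)) {
    v <- d[i] - borrow
    if (v < 0) { v <- v + BI_BASE; borrow <- 1 } else borrow <- 0
    d[i] <- v
  }
  d
}

bi_add <- function(a, b) {
  if (bi_is_zero(a)) return(b)
  if (bi_is_zero(b)) return(a)
  if (a$s == b$s) return(bi_norm(bi_add_abs(a, b), a$s))
  cmp <- bi_cmp_abs(a, b)
  if (cmp == 0L) return(bi_zero())
  if (cmp > 0L) bi_norm(bi_sub_abs(a, b), a$s) else bi_norm(bi_sub_abs(b, a), b$s)
}

bi_neg <- function(a) list(s = -a$s, d = a$d)
bi_sub <- function(a, b) bi_add(a, bi_neg(b))

bi_mul <- function(a, b) {
  if (bi_is_zero(a) || bi_is_zero(b)) return(bi_zero())
  na <- length(a$d); nb <- length(b$d)
  d <- numeric(na + nb)
  for (i in seq_len(na)) {
    # partial row with immediate carry so accumulated sums stay < 2^53
    row <- a$d[i] * b$d
    idx <- i:(i + nb - 1L)
    d[idx] <- d[idx] + row
    carry <- 0
    for (j in i:(na + nb)) {
      v <- d[j] + carry
      carry <- floor(v / BI_BASE)
      d[j] <- v - carry * BI_BASE
      if (carry == 0 && j >= i + nb) break
    }
  }
  bi_norm(d, a$s * b$s)
}

bi_mul_small <- function(a, m) { # 0 <= m < BI_BASE
  if (m == 0 || bi_is_zero(a)) return(bi_zero())
  bi_norm(a$d * m, a$s)
}

# leading-limb approximation: value ~ m * BASE^e
bi_approx <- function(a) {
  n <- length(a$d)
  if (n == 0L) return(list(m = 0, e = 0L))
  k <- min(3L, n)
  m <- sum(a$d[(n - k + 1L):n] * BI_BASE^(0:(k - 1L)))
  list(m = m, e = n - k)
}

# quotient and remainder of |a| / |b|; returns signed q (sign(a)*sign(b)), r with sign(a)
bi_divmod <- function(a, b) {
  if (bi_is_zero(b)) stop("division by zero")
  if (bi_cmp_abs(a, b) < 0L) return(list(q = bi_zero(), r = a))
  na <- length(a$d)
  qd <- numeric(na)
  r <- bi_zero()
  apb <- bi_approx(b)
  for (i in na:1) {
    r <- bi_norm(c(a$d[i], r$d), 1L)
    if (bi_is_zero(r)) r <- bi_zero()
    if (bi_cmp_abs(r, b) < 0L) { qd[i] <- 0; next }
    apr <- bi_approx(r)
    est <- (apr$m / apb$m) * BI_BASE^(apr$e - apb$e)
    qh <- min(BI_BASE - 1, max(0, floor(est)))
    prod <- bi_mul_small(b, qh)
    while (bi_cmp_abs(prod, r) > 0L) { qh <- qh - 1; prod <- bi_mul_small(b, qh) }
    repeat {
      nxt <- bi_mul_small(b, qh + 1)
      if (bi_cmp_abs(nxt, r) > 0L) break
      qh <- qh + 1; prod <- nxt
    }
    qd[i] <- qh
    r <- bi_norm(bi_sub_abs(r, prod), 1L)
  }
  q <- bi_norm(qd, a$s * b$s)
  if (!bi_is_zero(r)) r$s <- a$s
  list(q = q, r = r)
}

bi_gcd <- function(a, b) {
  a <- list(s = if (bi_is_zero(a)) 0L else 1L, d = a$d)
  b <- list(s = if (bi_is_zero(b)) 0L else 1L, d = b$d)
  while (!bi_is_zero(b)) {
    r <- bi_divmod(a, b)$r
    a <- b
    b <- list(s = if (bi_is_zero(r)) 0L else 1L, d = r$d)
  }
  a
}

bi_to_double <- function(a) {
  if (bi_is_zero(a)) return(0)
  v <- sum(a$d * BI_BASE^(seq_along(a$d) - 1L))
  a$s * v
}

bi_to_string <- function(a) {
  if (bi_is_zero(a)) return("0")
  n <- length(a$d)
  parts <- sprintf("%06d", a$d[-n])
  head <- format(a$d[n], scientific = FALSE, trim = TRUE)
  paste0(if (a$s < 0) "-" else "", paste(c(head, rev(parts)), collapse = ""))
}

bi_from_string <- function(s) {
  s <- trimws(s)
  neg <- startsWith(s, "-")
  if (neg || startsWith(s, "+")) s <- substring(s, 2L)
  if (!nzchar(s) || grepl("[^0-9]", s)) stop("not an integer string: ", s)
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  n <- nchar(s)
  d <- numeric(ceiling(n / 6))
  for (i in seq_along(d)) {
    lo <- max(1L, n - 6L * i + 1L)
    d[i] <- as.numeric(substr(s, lo, n - 6L * (i - 1L)))
  }
  bi_norm(d, if (neg) -1L else 1L)
}

## ---- rationals -------------------------------------------------------------

q_make <- function(num, den) {
  if (bi_is_zero(den)) stop("rational with zero denominator")
  if (den$s < 0L) { num <- bi_neg(num); den <- bi_neg(den) }
  if (bi_is_zero(num)) return(list(n = bi_zero(), d = bi(1)))
  g <- bi_gcd(num, den)
  if (!(length(g$d) == 1L && g$d[1] == 1)) {
    num <- bi_divmod(num, g)$q
    den <- bi_divmod(den, g)$q
  }
  list(n = num, d = den)
}

q_zero <- function() list(n = bi_zero(), d = bi(1))
q_one <- function() list(n = bi(1), d = bi(1))
q_is_zero <- function(q) bi_is_zero(q$n)

#' @noRd
q_from <- function(x) {
  if (is.list(x) && !is.null(x$n) && !is.null(x$d)) return(x)
  if (is.character(x)) return(q_parse(x))
  if (is.numeric(x)) {
    if (x == trunc(x)) return(q_make(bi(x), bi(1)))
    return(q_rationalize(x))
  }
  stop("cannot interpret as a rational: ", deparse(x))
}

q_parse <- function(s) {
  s <- trimws(s)
  if (grepl("/", s, fixed = TRUE)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed rational string: ", s)
    q_make(bi_from_string(parts[1]), bi_from_string(parts[2]))
  } else if (grepl("^[+-]?[0-9]+$", s)) {
    q_make(bi_from_string(s), bi(1))
  } else if (grepl("^[+-]?[0-9]*\\.[0-9]+$", s)) {
    q_rationalize(as.numeric(s))
  } else stop("malformed rational string: ", s)
}

# exact small-denominator representation of a decimal-entered value
q_rationalize <- function(x, max_den = 1e9) {
  stopifnot(is.finite(x))
  den <- 1
  while (abs(x * den - round(x * den)) > 1e-9 * max(1, abs(x * den)) && den < max_den)
    den <- den * 10
  if (abs(x * den - round(x * den)) > 1e-9 * max(1, abs(x * den)))
    stop("value has no short exact decimal form: ", x)
  q_make(bi(round(x * den)), bi(den))
}

q_add <- function(a, b) q_make(bi_add(bi_mul(a$n, b$d), bi_mul(b$n, a$d)), bi_mul(a$d, b$d))
q_sub <- function(a, b) q_add(a, q_neg(b))
q_neg <- function(a) list(n = bi_neg(a$n), d = a$d)
q_mul <- function(a, b) q_make(bi_mul(a$n, b$n), bi_mul(a$d, b$d))
q_div <- function(a, b) { if (q_is_zero(b)) stop("division by zero rational"); q_make(bi_mul(a$n, b$d), bi_mul(a$d, b$n)) }
q_abs <- function(a) list(n = list(s = abs(a$n$s), d = a$n$d), d = a$d)

q_cmp <- function(a, b) {
  diff <- q_sub(a, b)
  diff$n$s
}

q_eq <- function(a, b) q_cmp(a, b) == 0L

q_to_double <- function(q) {
  nn <- bi_to_double(q$n); dd <- bi_to_double(q$d)
  if (is.finite(nn) && is.finite(dd)) return(nn / dd)
  an <- bi_approx(q$n); ad <- bi_approx(q$d)
  sign(nn) * (an$m / ad$m) * BI_BASE^(an$e - ad$e)
}

q_to_string <- function(q) {
  ds <- bi_to_string(q$d)
  if (ds == "1") bi_to_string(q$n) else paste0(bi_to_string(q$n), "/", ds)
}
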