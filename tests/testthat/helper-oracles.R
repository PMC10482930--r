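# Independent oracles, written without reference to the package internals.

# Exhaustive stance propagation by the majority-retweet rule, straight from
# the definition: nested loops over users and edges, labels frozen per hop.
oracle_propagate <- function(edges, seeds, max_hops) {
  users <- unique(c(edges$retweeter, edges$source, seeds$user))
  lab <- stats::setNames(rep(NA_character_, length(users)), users)
  hop <- stats::setNames(rep(NA_integer_, length(users)), users)
  lab[seeds$user] <- seeds$stance
  hop[seeds$user] <- 0L
  for (h in seq_len(max_hops)) {
    frozen <- lab
    newly <- character(0)
    for (u in users) {
      if (!is.na(lab[[u]])) next
      pro <- 0L
      anti <- 0L
      for (j in seq_len(nrow(edges))) {
        if (edges$retweeter[j] != u) next
        s <- frozen[[edges$source[j]]]
        if (is.na(s)) next
        if (s == "pro_use") pro <- pro + edges$times[j]
        if (s == "anti_use") anti <- anti + edges$times[j]
      }
      if (pro + anti > 0L) {
        lab[[u]] <- if (pro > anti) "pro_use"
        else if (anti > pro) "anti_use" else "undetermined"
        hop[[u]] <- h
        newly <- c(newly, u)
      }
    }
    if (length(newly) == 0) break
  }
  keep <- !is.na(lab)
  out <- data.frame(user = names(lab)[keep], stance = unname(lab[keep]),
                    hop = unname(hop[keep]),
                    is_seed = names(lab)[keep] %in% seeds$user,
                    stringsAsFactors = FALSE)
  out[order(out$user), ]
}

# Brute-force truncated RBO from the defining sum, one pair at a time.
oracle_rbo_truncated <- function(s, t, p, depth) {
  total <- 0
  for (d in seq_len(depth)) {
    a_d <- length(intersect(s[seq_len(d)], t[seq_len(d)])) / d
    total <- total + p^(d - 1) * a_d
  }
  (1 - p) * total
}

# All ordered lists of length k over the symbols 1..n (permutation prefixes).
all_ranked_lists <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (x in remaining) rec(c(prefix, x), setdiff(remaining, x))
  }
  rec(integer(0), seq_len(n))
  out
}

# Numerical ALD maximum likelihood via general-purpose optimisation,
# independent of the closed-form profile fit.
oracle_ald_mle <- function(x) {
  nll <- function(par) {
    m <- par[1]
    lambda <- exp(par[2])
    kappa <- exp(par[3])
    z <- x - m
    -sum(log(lambda) - log(kappa + 1 / kappa) +
           ifelse(z >= 0, -lambda * kappa * z, (lambda / kappa) * z))
  }
  start <- c(stats::median(x), log(1 / stats::sd(x)), 0)
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  list(location = fit$par[1], scale = exp(fit$par[2]),
       asymmetry = exp(fit$par[3]), log_likelihood = -fit$value)
}

# Small deterministic event tibble builder for unit tests.
make_events <- function(retweeter, source, timestamp = NULL, stream = "en",
                        text = "", urls = NULL) {
  n <- length(retweeter)
  ts <- timestamp %||% (as.POSIXct("2021-06-01 00:00:00", tz = "UTC") +
                          seq_len(n) * 3600)
  tibble::tibble(
    event_id = sprintf("e%03d", seq_len(n)),
    timestamp = ts,
    retweeter_id = retweeter,
    source_user_id = source,
    stream_language = rep_len(stream, n),
    text = rep_len(text, n),
    urls = urls %||% rep(list(character(0)), n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
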