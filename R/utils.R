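`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integer mode of a vector
#'
#' Most frequent value; ties are broken towards the smallest value so the
#' result is deterministic.
#'
#' @param x integer vector.
#' @return The smallest most-frequent value, as an integer.
#' @keywords internal
int_mode <- function(x) {
  stopifnot(length(x) > 0)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])  # which.max takes first => smallest
}

# population standard deviation (divide by n, not n - 1)
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# truncated-normal sampler via inverse CDF; vectorised, never rejects
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(mean, n))
  a <- pnorm((lower - mean) / sd)
  b <- pnorm((upper - mean) / sd)
  mean + sd * qnorm(a + runif(n) * (b - a))
}

# moments of a normal truncated to [lower, upper]
truncnorm_moments <- function(mean, sd, lower, upper) {
  if (sd <= 0) return(list(mean = mean, sd = 0))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
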