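# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a stage name
#'
#' A single pipeline seed fans out to per-stage seeds by stable string
#' hashing, so each stage is reproducible independently of the order in
#' which stages run.  The result is always in `[0, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param name Character stage name.
#' @return A single integer seed.
#' @export
#' @examples
#' seed_stream(1, "admixture") != seed_stream(1, "cline")
seed_stream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483647
  as.integer((h + round(seed) %% 2147483647 * 7919) %% 2147483647)
}

# Draw one Dirichlet vector.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

# Great-circle distance in km (haversine, spherical Earth R = 6371 km).
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pondmix <- function(...) stop(..., call. = FALSE)
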