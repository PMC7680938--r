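#' Derive a reproducible substream seed
#'
#' Mixes a master seed with an arbitrary sequence of integers and strings
#' (replicate index, cycle, purpose label, ...) into a single integer seed
#' below 2^31.  Used throughout the package so that every source of
#' randomness has a named, reproducible substream and paired scenarios can
#' share streams (e.g. founder populations within a replicate).
#'
#' @param master Integer master seed.
#' @param ... Integers or character labels identifying the substream.
#' @return A positive integer scalar usable with [set.seed()].
#' @examples
#' substream_seed(1, 3, "cross")
#' @export
substream_seed <- function(master, ...) {
  parts <- list(master, ...)
  h <- 0
  for (p in parts) {
    if (is.character(p)) {
      v <- utf8ToInt(paste(p, collapse = "|"))
      p <- sum(v * seq_along(v))
    }
    for (x in as.numeric(p)) {
      h <- (h * 48271 + abs(x) + 11) %% 2147483587
    }
  }
  as.integer(h) + 1L
}

#' Map distance to recombination fraction (Haldane)
#'
#' Converts a genetic map distance in centimorgans to a recombination
#' fraction under Haldane's no-interference mapping function,
#' c = (1 - exp(-2 d)) / 2 with d in Morgans.
#'
#' @param d_cM Map distance in centimorgans (vectorised).
#' @return Recombination fraction in \[0, 0.5).
#' @examples
#' haldane_c(0.79)
#' @export
haldane_c <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  0.5 * (1 - exp(-2 * d_cM / 100))
}

## run `expr` with a local RNG state seeded by `seed` (NULL = use current)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## locate the python interpreter used for the coalescent backend
find_python <- function() {
  for (cand in c(Sys.getenv("MISLABELGS_PYTHON", ""), "python", "python3")) {
    if (!nzchar(cand)) next
    path <- Sys.which(cand)
    if (nzchar(path)) return(path)
  }
  stop("no python interpreter found; the founder simulator needs python ",
       "with msprime (set MISLABELGS_PYTHON to override lookup)")
}
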