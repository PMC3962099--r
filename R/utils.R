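# Misc internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller-visible RNG state afterwards. seed = NULL leaves the global
# stream untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
.check_count_scalar <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

# Canonical (alphabetical) 2-letter pair label.
#' @noRd
.pair_label <- function(a, b) {
  ifelse(a <= b, paste0(a, b), paste0(b, a))
}

# Accept a pair given as "EP" or c("E", "P"); return c(first, second)
# validated against the standard alphabet (order as given).
#' @noRd
.parse_pair <- function(pair) {
  if (length(pair) == 1L && is.character(pair) && nchar(pair) == 2L)
    pair <- strsplit(pair, "", fixed = TRUE)[[1L]]
  if (length(pair) != 2L || !all(pair %in% .AA20))
    stop("`pair` must be two standard one-letter residue codes, e.g. \"EP\"",
         call. = FALSE)
  if (pair[1L] == pair[2L])
    stop("pair must consist of two distinct residues", call. = FALSE)
  pair
}
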