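`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a mature miRNA identifier for matching
#'
#' User score tables frequently differ from miRBase names only in case
#' (e.g. `HSA-MIR-21-5P` vs `hsa-miR-21-5p`).  Comparisons throughout the
#' package therefore use a lowercased, whitespace-trimmed key; original
#' spellings are preserved for output.
#'
#' @param ids character vector of miRNA identifiers.
#' @return character vector of normalized lookup keys.
#' @examples
#' normalize_mirna_id("HSA-MIR-21-5P")
#' @export
normalize_mirna_id <- function(ids) {
  tolower(trimws(as.character(ids)))
}

# log(sum(exp(x))) without overflow; empty input -> -Inf
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# gzip-aware text connection helper (file() auto-detects compression)
open_text <- function(path) {
  con <- file(path, open = "rt")
  con
}
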