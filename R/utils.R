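# Internal helpers shared across modules.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to label permutation), approximately 0
#' for independent random labelings.
#'
#' @param a,b vectors of cluster/group labels of equal length.
#' @return A single numeric value in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")) # 1
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sij - expected) / (max_index - expected)
}

# Row-wise sample sd with n-1 denominator (vectorised).
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

# FNV-1a 32-bit hash of a character scalar; used for run manifests only.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h as a double to dodge
    # 32-bit signed overflow in bitwXor
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime 16777619; split into 16-bit
    # halves so every intermediate stays below 2^53
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Consistent abort with a module prefix.
stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x
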