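#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange desc filter mutate select bind_rows distinct
#' @importFrom purrr map map_dbl map_int map_chr map_lgl map2
NULL

# Canonical key for a protein/gene set: sorted, tab-free, stable across orderings.
set_key <- function(x) paste(sort(unique(x)), collapse = "\r")

# Read a text file as lines, dropping blank and `#`-comment lines but keeping
# the original line numbers so parse errors can cite them.
read_content_lines <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

# Population standard deviation (divisor n, not n - 1).
sd_pop <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  sqrt(sum((x - mu)^2) / n)
}

# All seeds are kept below 2^31 - 1 so they stay valid R integers.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + as.double(offset)) %% 2147483647)
}
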