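# Internal helpers: seeded evaluation, matrix validation, config hashing.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` uses the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Validate a genes x samples expression matrix: numeric, finite, uniquely
# named on both margins.
check_expression_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix (genes x samples)", arg),
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("'%s' must have gene rownames and sample colnames", arg),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop(sprintf("duplicated gene ids in '%s': %s", arg,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    stop(sprintf("duplicated sample ids in '%s': %s", arg,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' contains missing or non-finite values", arg),
         call. = FALSE)
  }
  invisible(x)
}

# Coerce a drug-response input (two-column data.frame or named numeric
# vector) to a named numeric vector of activity areas.
as_activity_area <- function(responses) {
  if (is.data.frame(responses)) {
    cols <- c("sample_id", "activity_area")
    if (!all(cols %in% names(responses))) {
      stop("response table needs columns 'sample_id' and 'activity_area'",
           call. = FALSE)
    }
    aa <- responses$activity_area
    names(aa) <- as.character(responses$sample_id)
  } else if (is.numeric(responses) && !is.null(names(responses))) {
    aa <- responses
  } else {
    stop("'responses' must be a data.frame or a named numeric vector",
         call. = FALSE)
  }
  if (anyDuplicated(names(aa))) {
    stop("duplicated sample ids in drug-response table", call. = FALSE)
  }
  if (!all(is.finite(aa))) stop("activity areas must be finite", call. = FALSE)
  if (any(aa < 0)) stop("activity areas must be non-negative", call. = FALSE)
  aa
}

# Row-wise sample standard deviation (denominator n - 1) without apply().
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

# Deterministic 31-bit polynomial string hash; used to stamp artifacts with
# a short fingerprint of their configuration.
string_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(config) {
  string_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE))
}
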