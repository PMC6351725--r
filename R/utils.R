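# Internal helpers shared across modules.

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's
# random state afterwards. seed = NULL leaves the RNG alone.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Dense numeric matrix view of the experiment data.
.denseData <- function(exp) {
  d <- exp@data
  if (is.matrix(d)) d else as.matrix(d)
}

# Replace the data matrix, honoring the sparse storage hint and keeping
# dimnames synchronized with the metadata tables.
.setData <- function(exp, m) {
  dimnames(m) <- list(rownames(exp@sampleMetadata),
                      rownames(exp@featureMetadata))
  exp@data <- if (exp@sparse) Matrix::Matrix(m, sparse = TRUE) else m
  exp
}

# Coerce character columns that parse as numbers for every non-missing
# value; everything else stays character. Metadata files carry mixed
# content, so this is decided column-by-column.
.coerceColumns <- function(df) {
  for (nm in names(df)) {
    v <- df[[nm]]
    if (!is.character(v)) next
    ok <- !is.na(v)
    if (!any(ok)) next
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num[ok])) df[[nm]] <- num
  }
  df
}

# Sort keys: numeric when every non-missing value parses as a number,
# otherwise character. Gives "2" < "10" the numeric reading.
.sortKey <- function(v) {
  if (is.numeric(v)) return(v)
  ch <- as.character(v)
  num <- suppressWarnings(as.numeric(ch))
  if (!anyNA(num[!is.na(ch)])) num else ch
}

# Stable polynomial hash of a string, used for reproducible category ->
# color assignment in heatmap tracks (documented: collisions map two
# categories to the same color, they never change across runs).
.stringHash <- function(s, mod) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  (h %% mod) + 1
}

.axisMatch <- function(axis) match.arg(axis, c("samples", "features"))

.stopInvalid <- function(...) stop(sprintf(...), call. = FALSE)

# TRUE when x is plain JSON-representable data: atomic vectors, NULL,
# and (possibly named) lists thereof. Closures, environments and other
# exotic objects are rejected before they reach the history log.
.jsonData <- function(x) {
  if (is.null(x) || (is.atomic(x) && !is.environment(x))) return(TRUE)
  if (is.list(x) && !is.object(x)) return(all(vapply(x, .jsonData, TRUE)))
  FALSE
}
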