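#' Long-format irregular longitudinal dataset
#'
#' Standard container for the package: one row per measurement with subject
#' id, raw measurement time, discretized grid index in `1..T`, continuous
#' outcome, a 0/1 dose indicator and the subject's dropout time (same units as
#' the raw time).  Grid indices are strictly increasing within subject and
#' every raw time is at most the subject's dropout time.
#'
#' @param df data.frame with columns `id`, `time`, `gridtime`, `y`, `dose`,
#'   `dropout`.
#' @param T grid length; defaults to the maximum observed grid index.
#' @param resolution grid resolution (raw time units per grid step).
#' @return object of class `long_data` (a data.frame with attributes `T` and
#'   `resolution`).
#' @export
long_data <- function(df, T = NULL, resolution = 1) {
  req <- c("id", "time", "gridtime", "y", "dose", "dropout")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("dataset contains no observations")
  if (!is.numeric(df$y) || anyNA(df$y)) stop("outcome y must be numeric without NAs")
  if (!all(df$dose %in% c(0, 1))) stop("dose must be a 0/1 indicator")
  df <- df[order(df$id, df$gridtime), , drop = FALSE]
  if (is.null(T)) T <- max(df$gridtime)
  if (any(df$gridtime < 1 | df$gridtime > T)) stop("grid indices must lie in 1..T")
  dup <- duplicated(df[, c("id", "gridtime")])
  if (any(dup)) stop("duplicate (subject, grid index) pairs; merge before construction")
  late <- tapply(df$time > df$dropout, df$id, any)
  if (any(late)) {
    stop("observed time after dropout for subject(s): ",
         paste(names(late)[late], collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, T = as.integer(T), resolution = resolution,
            class = c("long_data", "data.frame"))
}

#' @export
print.long_data <- function(x, ...) {
  cat(sprintf("long_data: %d observations, %d subjects, grid 1..%d (resolution %g)\n",
              nrow(x), length(unique(x$id)), attr(x, "T"), attr(x, "resolution")))
  NextMethod()
}

#' Grid length of a dataset
#' @param data a [long_data()] object.
#' @return integer `T`.
#' @export
grid_length <- function(data) attr(data, "T")

#' Read a long-format CSV and discretize times
#'
#' Raw times are divided by `resolution` and rounded half-up to the nearest
#' integer; index 0 (enrollment) is mapped to 1.  Duplicate (subject, grid
#' index) pairs after discretization are resolved by averaging their outcomes
#' with a warning.
#'
#' @param path CSV path.
#' @param columns named character vector mapping the required names
#'   `id`, `time`, `y`, `dose`, `dropout` to the file's column names.
#' @param resolution grid resolution (raw time units per grid step).
#' @param T optional grid length override (default: maximum observed index).
#' @return a [long_data()] object.
#' @export
read_long_csv <- function(path,
                          columns = c(id = "id", time = "time", y = "y",
                                      dose = "dose", dropout = "dropout"),
                          resolution = 1, T = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty file: ", path)
  need <- c("id", "time", "y", "dose", "dropout")
  miss <- setdiff(need, names(columns))
  if (length(miss)) stop("column map must name: ", paste(miss, collapse = ", "))
  absent <- setdiff(unname(columns[need]), names(raw))
  if (length(absent)) stop("missing columns in file: ", paste(absent, collapse = ", "))
  df <- data.frame(id = raw[[columns[["id"]]]],
                   time = as.numeric(raw[[columns[["time"]]]]),
                   y = raw[[columns[["y"]]]],
                   dose = raw[[columns[["dose"]]]],
                   dropout = as.numeric(raw[[columns[["dropout"]]]]))
  if (!is.numeric(df$y) || anyNA(df$y)) stop("non-numeric outcome column")
  df$gridtime <- pmax(1L, as.integer(floor(df$time / resolution + 0.5)))
  bad <- tapply(df$time > df$dropout, df$id, any)
  if (any(bad)) {
    stop("dropout earlier than an observation for subject(s): ",
         paste(names(bad)[bad], collapse = ", "))
  }
  if (anyDuplicated(df[, c("id", "gridtime")])) {
    warning("duplicate (subject, grid index) pairs after discretization; outcomes averaged")
    df <- stats::aggregate(cbind(time, y) ~ id + gridtime + dose + dropout,
                           data = df, FUN = mean)
  }
  long_data(df[, c("id", "time", "gridtime", "y", "dose", "dropout")],
            T = T, resolution = resolution)
}

#' Write a dataset to long-format CSV
#'
#' @param data a [long_data()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  stopifnot(inherits(data, "long_data"))
  utils::write.csv(as.data.frame(data)[, c("id", "time", "y", "dose", "dropout")],
                   path, row.names = FALSE)
  invisible(path)
}

# internal: pack a long_data object into the flat arrays the C++ kernels use
.pack_data <- function(data) {
  ids <- unique(data$id)
  idf <- factor(data$id, levels = ids)
  counts <- as.integer(table(idf))
  start <- c(0L, cumsum(counts))
  first <- !duplicated(idf)
  list(y = as.numeric(data$y),
       tidx = as.integer(data$gridtime) - 1L,
       start = start,
       N = length(ids),
       ids = ids,
       dose = data$dose[first],
       dropout = data$dropout[first],
       T = attr(data, "T"))
}
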