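# Particle coordinate tables: tab-separated, one-line header, columns
# (micrograph_id, x, y, peak, rank). Coordinates are 0-based pixel indices of
# the particle-box CENTER, (x, y) = (column, row); within one micrograph the
# ranks are 1..n with peak values non-increasing in rank.

COORD_COLS <- c("micrograph_id", "x", "y", "peak", "rank")

#' Write a particle coordinate table
#'
#' @param path output path (TSV).
#' @param records data.frame with columns `micrograph_id`, `x`, `y`, `peak`,
#'   `rank`; may have zero rows.
#' @return invisibly, `path`.
#' @export
write_coords <- function(path, records) {
  records <- as.data.frame(records)
  missing <- setdiff(COORD_COLS, names(records))
  if (length(missing)) stop("records lack columns: ", paste(missing, collapse = ", "))
  utils::write.table(records[COORD_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a particle coordinate table
#'
#' @param path path to a TSV written by [write_coords()].
#' @return data.frame with columns `micrograph_id` (character), `x`, `y`,
#'   `peak` (numeric) and `rank` (integer).
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("parse error at line 1: missing header")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, COORD_COLS)) {
    stop("parse error at line 1: expected header ",
         paste(COORD_COLS, collapse = "\t"))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(data.frame(micrograph_id = character(), x = numeric(),
                      y = numeric(), peak = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  out <- data.frame(micrograph_id = character(length(body)),
                    x = numeric(length(body)), y = numeric(length(body)),
                    peak = numeric(length(body)),
                    rank = integer(length(body)), stringsAsFactors = FALSE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    lineno <- i + 1L
    if (length(f) != 5) {
      stop("parse error at line ", lineno, ": expected 5 fields, got ", length(f))
    }
    num <- suppressWarnings(as.numeric(f[2:4]))
    rk <- suppressWarnings(as.integer(f[5]))
    if (any(is.na(num))) {
      bad <- COORD_COLS[1 + which(is.na(num))[1]]
      stop("parse error at line ", lineno, ": non-numeric ", bad)
    }
    if (is.na(rk) || rk < 1) {
      stop("parse error at line ", lineno, ": invalid rank")
    }
    out$micrograph_id[i] <- f[1]
    out$x[i] <- num[1]; out$y[i] <- num[2]; out$peak[i] <- num[3]
    out$rank[i] <- rk
  }
  out
}
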