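#' Write a trajectory to delimited text
#'
#' Format: `#`-prefixed `key=value` metadata lines (e.g.
#' `# temperature_C=37`, `# dt_s=0.01`, `# seed=42`), then a header line
#' `frame t_s x_nm y_nm photons` and tab-separated records. 1-D stepping
#' traces carry `y_nm = 0`.
#'
#' @param traj A `cargo_trajectory`.
#' @param path Output file path.
#' @param digits Numeric precision for positions/times.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, digits = 6) {
  meta <- trajectory_meta(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("temperature_C", "dt_s", "seed")) {
    val <- meta[[key]]
    if (!is.null(val) && !is.na(val)) {
      writeLines(sprintf("# %s=%s", key, format(val, digits = 15)), con)
    }
  }
  writeLines(paste(c("frame", "t_s", "x_nm", "y_nm", "photons"),
                   collapse = "\t"), con)
  df <- data.frame(frame = traj$frame,
                   t_s = signif(traj$t_s, digits + 4),
                   x_nm = round(traj$x_nm, digits),
                   y_nm = round(traj$y_nm, digits),
                   photons = traj$photons)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory from delimited text
#'
#' Parses the format written by [write_trajectory()]. Malformed headers,
#' missing columns, non-monotone time, negative photon counts and
#' unparseable records are rejected with line-numbered diagnostics.
#'
#' @param path Input file path.
#' @return A `cargo_trajectory` with the parsed metadata.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (i in meta_lines) {
    kv <- sub("^#\\s*", "", lines[i])
    m <- regmatches(kv, regexec("^([A-Za-z0-9_]+)=(.*)$", kv))[[1]]
    if (length(m) == 3) {
      v <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(v)) m[3] else v
    }
  }
  hdr_i <- setdiff(seq_along(lines), meta_lines)[1]
  if (is.na(hdr_i)) stop("line ", length(lines), ": no header line found")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  required <- c("frame", "t_s", "x_nm", "y_nm", "photons")
  missing_cols <- setdiff(required, hdr)
  if (length(missing_cols)) {
    stop("line ", hdr_i, ": header is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  body <- lines[(hdr_i + 1):length(lines)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("line ", hdr_i + 1, ": no data records")
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(hdr))
  if (length(bad)) {
    stop("line ", hdr_i + bad[1], ": expected ", length(hdr),
         " fields, found ", lengths(fields)[bad[1]])
  }
  mat <- do.call(rbind, fields)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- hdr
  df <- df[required]
  for (cc in required) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) {
      stop("line ", hdr_i + which(is.na(v))[1], ": non-numeric value in column ", cc)
    }
    df[[cc]] <- v
  }
  if (any(diff(df$t_s) <= 0)) {
    stop("line ", hdr_i + which(diff(df$t_s) <= 0)[1] + 1,
         ": time t_s is not strictly increasing")
  }
  if (any(df$photons < 0)) {
    stop("line ", hdr_i + which(df$photons < 0)[1], ": negative photon count")
  }
  new_trajectory(as.integer(df$frame), df$t_s, df$x_nm, df$y_nm,
                 df$photons, meta)
}
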