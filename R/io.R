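#' Read particle-grouped localization tables
#'
#' Reads a localization table in which every row is one localization and
#' particles are delimited by a shared \code{particle_id}. The CSV dialect
#' requires a header with columns \code{particle_id}, \code{x_nm},
#' \code{y_nm} and optionally \code{z_nm} (column order free, extra
#' columns ignored with a warning). Coordinates are nanometres.
#'
#' @param path path to the file.
#' @param dialect file format; only \code{"csv"} is supported.
#' @return A [ParticleSet-class]; one particle per distinct
#'   \code{particle_id}, rows grouped in file order, \code{scaleNm = 1},
#'   un-normalized. The spatial dimension is 3 when \code{z_nm} is
#'   present, else 2.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("particle_id,x_nm,y_nm", "A,0,0", "A,1,0", "B,5,5"), f)
#' ps <- readLocalizations(f)
#' length(ps)  # 2
#' @export
readLocalizations <- function(path, dialect = "csv") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  dialect <- match.arg(dialect, c("csv", "hdf5"))
  if (dialect == "hdf5")
    stop("the hdf5 dialect is not available in this build; ",
         "use dialect = \"csv\"")
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE),
    error = function(e) stop("cannot parse CSV file ", path, ": ",
                             conditionMessage(e)))
  if (!nrow(df)) stop("empty dataset: ", path, " has no data rows")
  required <- c("particle_id", "x_nm", "y_nm")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("format error: missing required column(s) ",
         paste(missing, collapse = ", "))
  has_z <- "z_nm" %in% names(df)
  coord_cols <- c("x_nm", "y_nm", if (has_z) "z_nm")
  extra <- setdiff(names(df), c(required, "z_nm"))
  if (length(extra))
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  for (cc in coord_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("parse error: non-numeric value '%s' in column %s, row %d",
                     v[bad[1]], cc, bad[1]))
      df[[cc]] <- vn
    }
    if (anyNA(df[[cc]]))
      stop(sprintf("parse error: missing value in column %s, row %d",
                   cc, which(is.na(df[[cc]]))[1]))
  }
  ids <- as.character(df$particle_id)
  uid <- unique(ids)  # file order
  coords <- as.matrix(df[coord_cols])
  parts <- lapply(uid, function(u)
    coords[ids == u, , drop = FALSE])
  particleSet(parts, ids = uid)
}

#' Write a ParticleSet as a localization table
#'
#' Writes one row per localization with columns \code{particle_id},
#' \code{x_nm}, \code{y_nm}[, \code{z_nm}]. Normalized sets are
#' de-normalized first (multiplied by \code{scaleNm}, centroids re-added)
#' so files are always in nanometres and round-trip through
#' [readLocalizations()].
#'
#' @param x a [ParticleSet-class].
#' @param path output path.
#' @param dialect file format; only \code{"csv"} is supported.
#' @return Invisibly, \code{path}.
#' @export
writeLocalizations <- function(x, path, dialect = "csv") {
  stopifnot(is(x, "ParticleSet"))
  if (!length(x)) stop("refusing to write an empty dataset")
  dialect <- match.arg(dialect, c("csv", "hdf5"))
  if (dialect == "hdf5")
    stop("the hdf5 dialect is not available in this build; ",
         "use dialect = \"csv\"")
  if (isNormalized(x)) x <- denormalizeParticles(x)
  n <- nLocalizations(x)
  coords <- do.call(rbind, particles(x))
  df <- data.frame(particle_id = rep(particleIds(x), n))
  cn <- c("x_nm", "y_nm", if (spatialDim(x) == 3L) "z_nm")
  for (j in seq_len(ncol(coords))) df[[cn[j]]] <- coords[, j]
  # full precision so the CSV round trip is exact on doubles
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open ", path,
                                           " for writing: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, function(v)
    if (is.numeric(v)) format(v, digits = 17, trim = TRUE,
                              scientific = FALSE) else v),
    sep = ","))
  writeLines(body, con)
  invisible(path)
}
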