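#' Construct a session bundle
#'
#' One imaging session: an activity raster, its movement epochs, optional
#' DF/F fluorescence traces, and metadata (animal id, age in postnatal days,
#' session id). All members must agree on the number of frames.
#'
#' @param raster an [activity_raster()].
#' @param movements a [movement_epochs()] table with matching
#'   \code{n_frames}.
#' @param traces optional numeric matrix of DF/F, same shape as
#'   \code{raster$activity}.
#' @param meta named list; must contain \code{animal_id}, \code{age_days}
#'   (postnatal day, in [3, 15]) and \code{session_id}.
#' @return object of class \code{session_bundle}.
#' @export
session_bundle <- function(raster, movements, traces = NULL, meta = list()) {
  stopifnot(inherits(raster, "activity_raster"),
            inherits(movements, "movement_epochs"))
  if (attr(movements, "n_frames") != n_frames(raster))
    stop("movements and raster disagree on n_frames")
  if (!is.null(traces)) {
    traces <- as.matrix(traces)
    if (!all(dim(traces) == dim(raster$activity)))
      stop("traces shape does not match raster")
  }
  meta <- utils::modifyList(
    list(animal_id = "animal1", age_days = 7, session_id = "session1"), meta)
  if (meta$age_days < 3 || meta$age_days > 15)
    stop("age_days must lie in [3, 15]")
  structure(list(raster = raster, movements = movements, traces = traces,
                 meta = meta),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle> ", x$meta$animal_id, " P", x$meta$age_days, " ",
      x$meta$session_id, ": ", sep = "")
  print(x$raster)
  cat("  ", nrow(x$movements), " movement epochs",
      if (!is.null(x$traces)) ", with DF/F traces", "\n", sep = "")
  invisible(x)
}

#' Write a session bundle to a directory of delimited tables
#'
#' The bundle dialect is one directory holding \code{transients.csv}
#' (cell, onset, peak), \code{movements.csv} (onset, offset, category),
#' \code{cells.csv} (cell, type), \code{meta.csv} (key, value) and, when
#' traces are present, \code{traces.csv} (cells x frames, no header).
#'
#' @param bundle a [session_bundle()].
#' @param path directory to create/overwrite.
#' @return \code{path}, invisibly.
#' @export
save_session <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  r <- bundle$raster
  tr <- do.call(rbind, lapply(seq_along(r$transients), function(c) {
    m <- r$transients[[c]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(cell = c, onset = m[, 1L], peak = m[, 2L])
  }))
  if (is.null(tr)) tr <- data.frame(cell = integer(), onset = integer(),
                                    peak = integer())
  utils::write.csv(tr, file.path(path, "transients.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$movements),
                   file.path(path, "movements.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell = seq_along(r$cell_types),
                              type = r$cell_types),
                   file.path(path, "cells.csv"), row.names = FALSE)
  meta <- data.frame(key = c("animal_id", "age_days", "session_id",
                             "n_frames", "frame_rate"),
                     value = c(bundle$meta$animal_id,
                               format(bundle$meta$age_days, digits = 15),
                               bundle$meta$session_id,
                               n_frames(r),
                               format(r$frame_rate, digits = 15)))
  utils::write.csv(meta, file.path(path, "meta.csv"), row.names = FALSE)
  if (!is.null(bundle$traces))
    utils::write.table(bundle$traces, file.path(path, "traces.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a session bundle from a bundle directory
#'
#' Reads the CSV dialect written by [save_session()], validates every
#' invariant (shapes, interval ordering, categories) and drops cells
#' labelled \code{"noise"}.
#'
#' @param path bundle directory.
#' @return a validated [session_bundle()].
#' @export
load_session <- function(path) {
  need <- c("transients.csv", "movements.csv", "cells.csv", "meta.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("bundle at ", path, " is missing: ", paste(missing, collapse = ", "))
  meta_tab <- utils::read.csv(file.path(path, "meta.csv"),
                              stringsAsFactors = FALSE)
  if (!all(c("key", "value") %in% names(meta_tab)))
    stop("meta.csv must have columns key,value")
  meta <- stats::setNames(as.list(meta_tab$value), meta_tab$key)
  for (k in c("n_frames", "frame_rate", "age_days")) {
    if (is.null(meta[[k]])) stop("meta.csv missing key: ", k)
    meta[[k]] <- as.numeric(meta[[k]])
    if (is.na(meta[[k]])) stop("meta.csv key ", k, " is not numeric")
  }
  nf <- as.integer(meta$n_frames)
  cells <- utils::read.csv(file.path(path, "cells.csv"),
                           stringsAsFactors = FALSE)
  if (!all(c("cell", "type") %in% names(cells)))
    stop("cells.csv must have columns cell,type")
  tr <- utils::read.csv(file.path(path, "transients.csv"),
                        stringsAsFactors = FALSE)
  if (!all(c("cell", "onset", "peak") %in% names(tr)))
    stop("transients.csv must have columns cell,onset,peak")
  if (nrow(tr) && any(tr$peak < tr$onset))
    stop("transients.csv: peak before onset")
  if (nrow(tr) && (any(tr$onset < 1) || any(tr$peak > nf)))
    stop("transients.csv: frame index outside [1, n_frames]")
  if (nrow(tr) && !all(tr$cell %in% cells$cell))
    stop("transients.csv refers to unknown cell ids")
  transients <- lapply(cells$cell, function(c) {
    sub <- tr[tr$cell == c, , drop = FALSE]
    cbind(onset = as.integer(sub$onset), peak = as.integer(sub$peak))
  })
  mv <- utils::read.csv(file.path(path, "movements.csv"),
                        stringsAsFactors = FALSE)
  if (!all(c("onset", "offset", "category") %in% names(mv)))
    stop("movements.csv must have columns onset,offset,category")
  raster <- activity_raster(transients, n_frames = nf,
                            frame_rate = meta$frame_rate,
                            cell_types = cells$type)
  movements <- movement_epochs(mv$onset, mv$offset, mv$category,
                               n_frames = nf)
  traces <- NULL
  tf <- file.path(path, "traces.csv")
  if (file.exists(tf)) {
    traces <- as.matrix(utils::read.table(tf, sep = ","))
    dimnames(traces) <- NULL
    noise <- cells$type == "noise"
    if (any(noise)) traces <- traces[!noise, , drop = FALSE]
  }
  session_bundle(raster, movements, traces,
                 meta = list(animal_id = as.character(meta$animal_id),
                             age_days = meta$age_days,
                             session_id = as.character(meta$session_id)))
}
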