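#' Write a release curve to CSV
#'
#' Long format with columns `time,fraction` and, when replicates are
#' present, one extra row block per replicate with a `replicate` column.
#'
#' @param curve A [release_curve()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_release_csv <- function(curve, path) {
  stopifnot(inherits(curve, "release_curve"))
  if (is.null(curve$replicates)) {
    df <- data.frame(time = curve$times, fraction = curve$fraction)
  } else {
    k <- ncol(curve$replicates)
    df <- data.frame(
      time = rep(curve$times, k),
      fraction = as.vector(curve$replicates),
      replicate = rep(seq_len(k), each = length(curve$times))
    )
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a release curve from CSV
#'
#' Accepts the dialect of [write_release_csv()]: columns `time`,
#' `fraction`, optional `replicate`. With replicates, the `fraction`
#' field of the returned curve is the replicate mean.
#'
#' @param path CSV path.
#' @return A [release_curve()].
#' @export
read_release_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "fraction") %in% names(df)))
    stop("release CSV needs columns time,fraction[,replicate]",
         call. = FALSE)
  if (is.null(df$replicate)) {
    return(release_curve(df$time, df$fraction))
  }
  reps <- sort(unique(df$replicate))
  times <- sort(unique(df$time))
  mat <- sapply(reps, function(r) {
    sub <- df[df$replicate == r, ]
    sub$fraction[match(times, sub$time)]
  })
  mat <- matrix(mat, nrow = length(times))
  colnames(mat) <- paste0("rep", reps)
  release_curve(times, rowMeans(mat), replicates = mat)
}

#' Write a coating run to CSV
#'
#' Columns `condition,layer,step,loss_mass`; the content basis is stored
#' in a `content_basis` column (constant per run).
#'
#' @param run A [coating_run()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_coating_csv <- function(run, path) {
  stopifnot(inherits(run, "coating_run"))
  df <- data.frame(condition = run$condition, run$steps,
                   content_basis = run$content_basis)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a coating run from CSV
#'
#' @param path CSV path in the dialect of [write_coating_csv()].
#' @return A [coating_run()].
#' @export
read_coating_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("condition", "layer", "step", "loss_mass", "content_basis")
  if (!all(need %in% names(df)))
    stop("coating CSV needs columns condition,layer,step,loss_mass,content_basis",
         call. = FALSE)
  coating_run(condition = as.character(df$condition[1]),
              steps = df[, c("layer", "step", "loss_mass")],
              content_basis = df$content_basis[1])
}

#' Write a JSON run manifest
#'
#' Serialises a configuration list (seed, geometry, grid, paths, ...) so
#' a generated dataset or model run can be reconstructed exactly.
#' S3 objects from this package are flattened to plain lists.
#'
#' @param config Named list (may contain package objects).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
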