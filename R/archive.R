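# Run archives: plain-text persistence of trajectories, flux runs, and FFS
# results, with checksums, seeds, and RNG counters so a run can be resumed
# or re-analyzed from the archive alone.

write_tsv <- function(df, path) {
  # %.17g guarantees an exact double round trip through the text file
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
}

#' Write a run archive
#'
#' Persists a `fh_trajectory`, `fh_flux`, or `fh_ffs` object as a directory
#' of tab-separated tables plus a JSON metadata file holding the object
#' class, seeds, RNG counters, and MD5 checksums of every table.  Floats
#' are written at full double precision.
#'
#' @param x Object to archive.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_archive <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- options(digits = 17); on.exit(options(old))
  meta <- list(class = class(x)[1], version = "1")
  if (inherits(x, "fh_trajectory")) {
    write_tsv(x$snapshots, file.path(dir, "snapshots.tsv"))
    write_tsv(x$hops, file.path(dir, "hops.tsv"))
    meta$dt <- x$dt
    meta$steps_done <- x$steps_done
    meta$final_state <- snapshot_to_state(x$final)
    meta$final_time <- x$final$time
    meta$seeds <- c(x$thermo$seed_noise, x$thermo$seed_hop)
  } else if (inherits(x, "fh_flux")) {
    write_tsv(x$points, file.path(dir, "points.tsv"))
    meta$phi <- x$phi; meta$N0 <- x$N0
    meta$time_counted <- x$time_counted
    meta$method <- x$method
    meta$counters <- as.list(x$counters)
  } else if (inherits(x, "fh_ffs")) {
    write_tsv(x$summary, file.path(dir, "summary.tsv"))
    write_tsv(x$flux$points, file.path(dir, "points.tsv"))
    write_tsv(x$paths[c("path_id", "duration", "n_hops")],
              file.path(dir, "paths.tsv"))
    for (i in seq_along(x$cycles)) {
      cyc <- x$cycles[[i]]
      if (!is.null(cyc) && nrow(cyc$accepted) > 0)
        write_tsv(cyc$accepted, file.path(dir, sprintf("cycle_%02d.tsv", i)))
    }
    meta$k_AB <- x$k_AB; meta$dk_AB <- x$dk_AB
    meta$phi <- x$flux$phi; meta$N0 <- x$flux$N0
    meta$time_counted <- x$flux$time_counted
    meta$flux_method <- x$flux$method
  } else {
    abort("write_archive() supports fh_trajectory, fh_flux, and fh_ffs")
  }
  tsvs <- list.files(dir, pattern = "\\.tsv$")
  meta$checksums <- as.list(tools::md5sum(file.path(dir, tsvs)))
  names(meta$checksums) <- tsvs
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a run archive
#'
#' Validates the stored checksums and reconstructs the archived tables.
#'
#' @param dir Archive directory.
#' @return A list with `meta` and the stored tibbles.
#' @export
read_archive <- function(dir) {
  mpath <- file.path(dir, "meta.json")
  if (!file.exists(mpath)) abort(paste0("no archive at ", dir))
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  for (f in names(meta$checksums)) {
    got <- unname(tools::md5sum(file.path(dir, f)))
    if (!identical(got, meta$checksums[[f]]))
      abort(paste0("archive checksum mismatch for ", f))
  }
  tabs <- lapply(names(meta$checksums),
                 function(f) read_tsv(file.path(dir, f)))
  names(tabs) <- sub("\\.tsv$", "", names(meta$checksums))
  c(list(meta = meta), tabs)
}
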