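# CSV interchange. Every file carries '#'-prefixed header comments with
# schema version, units and producing parameters, so real and synthetic
# data flow identically through the pipeline.

.SCHEMA <- "clustrack-csv-1"

.writeCommented <- function(df, path, comments) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", c(.SCHEMA, comments)), con)
    utils::write.csv(df, con, row.names = FALSE)
}

.readCommented <- function(path) {
    utils::read.csv(path, comment.char = "#")
}

#' Write / read a localization table as commented CSV
#'
#' Columns: frame (0-based), molecule, x, y (nm, origin at the corner of
#' pixel (0,0)), sigma (nm), channel.
#'
#' @param locs a [LocalizationTable-class].
#' @param path file path.
#' @return `readLocalizations` returns a [LocalizationTable-class].
#' @export
writeLocalizations <- function(locs, path) {
    stopifnot(is(locs, "LocalizationTable"))
    .writeCommented(locs@locs, path, c(
        "localizations; x,y in nm from top-left corner of pixel (0,0); frame 0-based",
        sprintf("pixelSize_nm=%g tExp_s=%g tInt_s=%g nFrames=%d",
                locs@pixelSize, locs@schedule@tExp, locs@schedule@tInt,
                locs@schedule@nFrames)))
    invisible(path)
}

#' @rdname writeLocalizations
#' @export
readLocalizations <- function(path) {
    hdr <- readLines(path, n = 5L)
    hdr <- hdr[startsWith(hdr, "#")]
    par <- regmatches(hdr, gregexpr("[a-zA-Z_]+=[-0-9.eE]+", hdr))
    par <- unlist(par)
    kv <- strsplit(par, "=")
    vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                            vapply(kv, `[`, "", 1))
    df <- .readCommented(path)
    new("LocalizationTable", locs = df,
        pixelSize = unname(vals["pixelSize_nm"]),
        schedule = acquisitionSchedule(unname(vals["tExp_s"]),
                                       unname(vals["tInt_s"]),
                                       as.integer(vals["nFrames"])))
}

#' Write / read a track set as commented CSV
#'
#' @param trackset a [TrackSet-class].
#' @param path file path.
#' @return `readTracks` returns a [TrackSet-class].
#' @export
writeTracks <- function(trackset, path) {
    stopifnot(is(trackset, "TrackSet"))
    .writeCommented(trackset@spots, path, c(
        "tracks; x,y in nm; frame 0-based",
        sprintf("tInt_s=%g", trackset@tInt)))
    invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path) {
    hdr <- readLines(path, n = 4L)
    m <- regmatches(hdr, regexpr("tInt_s=[-0-9.eE]+", hdr))
    tInt <- as.numeric(sub("tInt_s=", "", m[m != ""][1]))
    new("TrackSet", spots = .readCommented(path), tInt = tInt)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Photon counts are stored as 16-bit samples after division by `scale`
#' (stated here, fixed across the package), so integer photon counts up to
#' 65535 round-trip exactly.
#'
#' @param stack an [ImageStack-class].
#' @param path file path.
#' @param tExp,tInt schedule to attach on read, seconds.
#' @param pixelSize pixel size to attach on read, nm.
#' @param channel channel name to attach on read.
#' @param scale photon value mapped to the 16-bit maximum (default 65535).
#' @return `readImageStack` returns an [ImageStack-class].
#' @export
writeImageStack <- function(stack, path, scale = 65535) {
    stopifnot(is(stack, "ImageStack"))
    pages <- lapply(seq_len(dim(stack@data)[3]), function(f)
        pmin(stack@data[, , f] / scale, 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path, tExp = 0.2, tInt = 0.2, pixelSize = 160,
                           channel = "activated", scale = 65535) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (f in seq_along(pages)) arr[, , f] <- round(pages[[f]] * scale)
    new("ImageStack", data = arr, pixelSize = pixelSize, channel = channel,
        schedule = acquisitionSchedule(tExp, tInt, length(pages)))
}
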