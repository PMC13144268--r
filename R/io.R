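## Image export: 8-bit grayscale training images (png package), 16-bit colour
## reader images ("Cool" colormap) through a minimal built-in PNG encoder
## (no installed R package writes 16-bit PNG), and cohort directory layout.

#' Export a unit-range image as 8-bit grayscale PNG
#'
#' Quantisation is round(value * 255) half away from zero; reading the file
#' back returns exactly integer/255.
#'
#' @param image numeric matrix with values in \[0, 1\].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_png8 <- function(image, path) {
  if (!is.numeric(image) || anyNA(image) || min(image) < 0 || max(image) > 1)
    stop("image values must lie in [0, 1]")
  q <- round_half_away(image * 255)
  png::writePNG(q / 255, path)
  invisible(path)
}

## -- minimal 16-bit PNG encoder ----------------------------------------------

.be4 <- function(x) {
  as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256, x %/% 256 %% 256,
           x %% 256))
}

.png_chunk <- function(type, data = raw(0)) {
  body <- c(charToRaw(type), data)
  c(.be4(length(data)), body, .be4(.crc32_raw(body)))
}

# rgb: array (H, W, 3) in [0,1]; writes a 16-bit truecolor PNG.
write_png16_rgb <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L,
            min(rgb) >= 0, max(rgb) <= 1)
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  v <- round_half_away(rgb * 65535)
  hi <- v %/% 256; lo <- v %% 256
  scan <- vector("list", H)
  for (r in seq_len(H)) {
    A <- array(0, dim = c(2L, 3L, W))         # byte, channel, pixel
    A[1L, , ] <- t(hi[r, , ]); A[2L, , ] <- t(lo[r, , ])
    scan[[r]] <- c(as.raw(0L), as.raw(A))     # filter type 0 + samples
  }
  idat <- memCompress(do.call(c, scan), type = "gzip")  # zlib stream
  ihdr <- c(.be4(W), .be4(H), as.raw(c(16L, 2L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           .png_chunk("IHDR", ihdr), .png_chunk("IDAT", idat),
           .png_chunk("IEND"))
  writeBin(out, path)
  invisible(path)
}

# "Cool" colormap: linear cyan (0,1,1) -> magenta (1,0,1).
cool_colormap <- function(t) {
  d <- dim(t)
  out <- array(0, dim = c(d[1], d[2], 3L))
  out[, , 1] <- t; out[, , 2] <- 1 - t; out[, , 3] <- 1
  out
}

#' Export the 3-slice reader image for visual assessment
#'
#' The three reader slices are montaged side by side, windowed over the full
#' intensity range of the stack, mapped through the "Cool" colormap
#' (cyan to magenta), integer-magnified, and written as 16-bit colour PNG.
#'
#' @param selection a [select_slices()] result (uses `reader_indices`).
#' @param stack 3-D image stack (slices x rows x cols), e.g. a long stack or
#'   a model-enhanced stack.
#' @param path output file path.
#' @param magnify integer pixel-replication factor for display.
#' @return the path, invisibly.
#' @export
export_reader_image <- function(selection, stack, path, magnify = 3L) {
  idx <- selection$reader_indices
  stopifnot(length(idx) == 3L, all(idx >= 1), all(idx <= dim(stack)[1]))
  sn <- normalize_case(stack)
  montage <- do.call(cbind, lapply(idx, function(s) sn[s, , ]))
  big <- kronecker(montage, matrix(1, magnify, magnify))
  write_png16_rgb(cool_colormap(big), path)
  invisible(path)
}

#' Export a blinded set of reader images with a key file
#'
#' Filenames carry only a random token; the mapping token -> (case, method)
#' is persisted to `key.csv` in the output directory.
#'
#' @param stacks named list: `stacks[[method_id]][[case_id]]` is a 3-D stack.
#' @param selections named list of [select_slices()] results per case.
#' @param dir output directory (created if needed).
#' @param seed seed for token randomisation.
#' @param magnify passed to [export_reader_image()].
#' @return data frame (token, case_id, method_id), invisibly.
#' @export
export_reader_set <- function(stacks, selections, dir, seed = 1L,
                              magnify = 3L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- expand.grid(case_id = names(selections),
                      method_id = names(stacks),
                      stringsAsFactors = FALSE)
  tokens <- with_seed(seed, sprintf("img_%06d", sample.int(999999L,
                                                           nrow(grid))))
  key <- cbind(token = tokens, grid)
  for (i in seq_len(nrow(key))) {
    export_reader_image(selections[[key$case_id[i]]],
                        stacks[[key$method_id[i]]][[key$case_id[i]]],
                        file.path(dir, paste0(key$token[i], ".png")),
                        magnify = magnify)
  }
  utils::write.csv(key, file.path(dir, "key.csv"), row.names = FALSE)
  invisible(key)
}

#' Write a cohort to disk as PNG slices plus a manifest
#'
#' Layout: `<case>/short/slice_###.png` and `<case>/long/slice_###.png`
#' (8-bit grayscale, each stack normalised by its own maximum), plus
#' `manifest.csv` with case_id, hemisphere, truth_score, seed.
#'
#' @param cohort a `dat_cohort`.
#' @param dir output directory.
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dat_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pair in cohort$pairs) {
    for (kind in c("short", "long")) {
      sub <- file.path(dir, pair$case_id, kind)
      dir.create(sub, recursive = TRUE, showWarnings = FALSE)
      stack <- normalize_case(pair[[paste0(kind, "_stack")]])
      for (s in seq_len(dim(stack)[1]))
        export_png8(stack[s, , ], file.path(sub, sprintf("slice_%03d.png", s)))
    }
  }
  manifest <- cbind(cohort$truth[c("case_id", "hemisphere")],
                    truth_score = cohort$truth$score, seed = cohort$seed)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
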