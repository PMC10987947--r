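# Optional reader for Ninapro DB2 MATLAB containers.
#
# DB2 stores, per subject, 12-channel sEMG at 2 kHz together with 22-channel
# CyberGlove kinematics (upsampled to the sEMG clock in the distributed
# files), a `stimulus` movement-label vector and a `repetition` trial-label
# vector. The loader segments the arrays at the label boundaries and maps
# the selected movements and glove channels to subject_recording values.
# A small MAT-file (level 5) parser for numeric arrays is included, so no
# MATLAB bridge is needed; never required by the rest of the package.

#' Selection of movements, glove channels and subjects for DB2
#'
#' The experiment protocol uses 6 grasping movements, 10 of the 22 glove
#' channels and 10 subjects, but the exact identifiers are a choice the user
#' must make for their analysis. The defaults below are documented
#' placeholders, not an authoritative reconstruction: movements `1, 2, 3, 5,
#' 6, 9` index grasp-type movements within the grasping exercise's stimulus
#' numbering, and glove channels `2, 3, 5, 6, 8, 9, 12, 13, 16, 17` are the
#' metacarpophalangeal/proximal-interphalangeal sensor pairs of the five
#' digits on the 22-sensor CyberGlove layout. Override both to match your
#' setup.
#'
#' @param movement_ids exactly 6 stimulus identifiers.
#' @param glove_channel_ids exactly 10 of the 22 glove channels.
#' @param subject_ids subject identifiers (default 1..10).
#' @return Object of class `db2_selection`.
#' @export
db2_selection <- function(movement_ids = c(1, 2, 3, 5, 6, 9),
                          glove_channel_ids = c(2, 3, 5, 6, 8, 9, 12, 13, 16, 17),
                          subject_ids = 1:10) {
  if (length(movement_ids) != 6) stop("exactly 6 movement ids are required")
  if (length(glove_channel_ids) != 10) {
    stop("exactly 10 glove channels are required")
  }
  if (any(glove_channel_ids < 1 | glove_channel_ids > 22)) {
    stop("glove channels must lie in 1..22")
  }
  structure(list(movement_ids = movement_ids,
                 glove_channel_ids = glove_channel_ids,
                 subject_ids = subject_ids),
            class = "db2_selection")
}

#' Load one DB2 file (or in-memory container) as subject recordings
#'
#' @param x path to a level-5 `.mat` file, or a named list with numeric
#'   arrays `emg` (samples x 12), `glove` (samples x 22), `stimulus` and
#'   `repetition` (samples), all on the 2 kHz clock.
#' @param selection a [db2_selection()].
#' @param subject_id identifier recorded on the output (default taken from a
#'   `subject` array when present, else `"db2"`).
#' @param fs sampling rate of the arrays (default 2000).
#' @return List of [subject_recording()], one per (selected movement x
#'   repetition 1..6) segment found; rest periods (stimulus 0) are excluded.
#'   Glove angles keep the file's sampling rate.
#' @export
load_db2_recording <- function(x, selection = db2_selection(),
                               subject_id = NULL, fs = 2000) {
  stopifnot(inherits(selection, "db2_selection"))
  cont <- if (is.character(x)) read_mat_v5(x) else x
  for (nm in c("emg", "glove", "stimulus", "repetition")) {
    if (is.null(cont[[nm]])) stop("missing array in DB2 container: ", nm)
  }
  emg <- as.matrix(cont$emg)
  glove <- as.matrix(cont$glove)
  stimulus <- as.integer(as.numeric(cont$stimulus))
  repetition <- as.integer(as.numeric(cont$repetition))
  if (ncol(emg) != 12) {
    stop(sprintf("expected 12 emg channels, file has %d", ncol(emg)))
  }
  if (ncol(glove) < max(selection$glove_channel_ids)) {
    stop("glove array has fewer channels than the selection requires")
  }
  if (is.null(subject_id)) {
    subject_id <- if (!is.null(cont$subject)) {
      paste0("s", as.integer(cont$subject[1L]))
    } else "db2"
  }
  missing_mv <- setdiff(selection$movement_ids, unique(stimulus))
  if (length(missing_mv)) {
    stop("movement id(s) absent from file: ",
         paste(missing_mv, collapse = ", "))
  }
  # contiguous runs of a constant stimulus label are the trial segments
  r <- rle(stimulus)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    mv <- r$values[i]
    if (!(mv %in% selection$movement_ids)) next
    seg <- starts[i]:ends[i]
    rep_id <- max(repetition[seg])
    if (rep_id < 1L || rep_id > 6L) next
    out[[length(out) + 1L]] <- subject_recording(
      subject_id = subject_id, movement_id = mv, trial_id = rep_id,
      emg = emg[seg, , drop = FALSE],
      angles = glove[seg, selection$glove_channel_ids, drop = FALSE],
      fs_emg = fs, fs_angles = fs)
  }
  out
}

## ---- minimal MAT-file level 5 parser ---------------------------------------

mi_read_numeric <- function(raw, type) {
  switch(as.character(type),
    `1` = readBin(raw, "integer", length(raw), size = 1L, signed = TRUE),
    `2` = readBin(raw, "integer", length(raw), size = 1L, signed = FALSE),
    `3` = readBin(raw, "integer", length(raw) %/% 2L, size = 2L,
                  signed = TRUE, endian = "little"),
    `4` = readBin(raw, "integer", length(raw) %/% 2L, size = 2L,
                  signed = FALSE, endian = "little"),
    `5` = readBin(raw, "integer", length(raw) %/% 4L, size = 4L,
                  endian = "little"),
    `6` = {                           # uint32 can exceed R's integer range
      b <- matrix(as.numeric(raw), nrow = 4L)
      b[1, ] + 256 * (b[2, ] + 256 * (b[3, ] + 256 * b[4, ]))
    },
    `7` = readBin(raw, "numeric", length(raw) %/% 4L, size = 4L,
                  endian = "little"),
    `9` = readBin(raw, "numeric", length(raw) %/% 8L, size = 8L,
                  endian = "little"),
    stop("unsupported MAT numeric type ", type))
}

# read the next data element starting at offset `pos` (1-based); returns
# list(type, bytes, next_pos)
mat_next_element <- function(raw, pos) {
  tag <- readBin(raw[pos:(pos + 3L)], "integer", 1L, size = 4L,
                 endian = "little")
  small_size <- bitwAnd(bitwShiftR(tag, 16L), 0xffffL)
  if (small_size > 0L) {               # small data element format
    type <- bitwAnd(tag, 0xffffL)
    bytes <- raw[(pos + 4L):(pos + 3L + small_size)]
    return(list(type = type, bytes = bytes, next_pos = pos + 8L))
  }
  type <- tag
  nb <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1L, size = 4L,
                endian = "little")
  bytes <- if (nb > 0L) raw[(pos + 8L):(pos + 7L + nb)] else raw(0)
  # data are padded to an 8-byte boundary, except compressed elements,
  # which common writers emit with their exact byte size
  adv <- if (type == 15L) nb else nb + (8L - nb %% 8L) %% 8L
  list(type = type, bytes = bytes, next_pos = pos + 8L + adv)
}

# parse one miMATRIX payload into a named numeric matrix (or NULL if the
# array class is not a supported numeric type)
mat_parse_matrix <- function(bytes) {
  pos <- 1L
  flags <- mat_next_element(bytes, pos)      # array flags (miUINT32 x2)
  pos <- flags$next_pos
  class_id <- as.integer(flags$bytes[1L])
  dims_el <- mat_next_element(bytes, pos)
  pos <- dims_el$next_pos
  dims <- readBin(dims_el$bytes, "integer", length(dims_el$bytes) %/% 4L,
                  size = 4L, endian = "little")
  name_el <- mat_next_element(bytes, pos)
  pos <- name_el$next_pos
  name <- rawToChar(name_el$bytes[name_el$bytes != as.raw(0)])
  if (!(class_id %in% 6:13) || length(dims) != 2L) {
    return(list(name = name, value = NULL))
  }
  data_el <- mat_next_element(bytes, pos)
  vals <- mi_read_numeric(data_el$bytes, data_el$type)
  list(name = name, value = matrix(as.numeric(vals), dims[1L], dims[2L]))
}

#' Read numeric arrays from a MAT-file (level 5)
#'
#' Minimal little-endian reader covering what DB2 files contain: 2-D numeric
#' arrays of any storage type, plain or zlib-compressed. Other array classes
#' (cells, structs, characters) are skipped.
#'
#' @param path path to the `.mat` file.
#' @return Named list of numeric matrices.
#' @export
read_mat_v5 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128L) stop("not a MAT-file (too short): ", path)
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") {
    stop("unsupported MAT-file endianness/marker: ", endian)
  }
  out <- list()
  pos <- 129L
  while (pos + 7L <= length(raw)) {
    el <- mat_next_element(raw, pos)
    pos <- el$next_pos
    payload <- el
    if (el$type == 15L) {              # miCOMPRESSED wraps one element
      inflated <- memDecompress(el$bytes, type = "gzip")
      payload <- mat_next_element(inflated, 1L)
    }
    if (payload$type != 14L) next      # only miMATRIX elements carry arrays
    parsed <- mat_parse_matrix(payload$bytes)
    if (!is.null(parsed$value) && nzchar(parsed$name)) {
      out[[parsed$name]] <- parsed$value
    }
  }
  out
}
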