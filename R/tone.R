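#' Default emotion-to-band mapping
#'
#' The speech-emotion recognizer upstream of this pipeline emits one of five
#' emotion labels per phrase: joy, boredom, anger, sadness, neutral. The
#' pipeline folds these into the trinary valence band used by the other two
#' channels: joy is the only positively valenced emotion (+1), neutral maps to
#' 0, and anger, sadness and boredom are negative (-1).
#'
#' @return Named integer vector over the five recognized emotion names.
#' @export
default_band_map <- function() {
  c(joy = 1L, neutral = 0L, anger = -1L, sadness = -1L, boredom = -1L)
}

validate_band_map <- function(band_map) {
  recognized <- names(default_band_map())
  if (is.null(names(band_map)) || !setequal(names(band_map), recognized)) {
    stop(sprintf("band map must assign exactly the recognized emotions: %s",
                 paste(recognized, collapse = ", ")), call. = FALSE)
  }
  if (any(!band_map %in% c(-1L, 0L, 1L))) {
    stop("band values must be -1, 0 or +1", call. = FALSE)
  }
  stats::setNames(as.integer(band_map[recognized]), recognized)
}

#' Map emotion labels to tone bands
#'
#' @param label Character vector of emotion names (case-insensitive).
#' @param band_map Named integer map over the five recognized emotions;
#'   defaults to [default_band_map()].
#' @return Integer vector of bands in \{-1, 0, +1\}.
#' @examples
#' map_emotion(c("Joy", "sadness"))
#' @export
map_emotion <- function(label, band_map = default_band_map()) {
  band_map <- validate_band_map(band_map)
  key <- tolower(as.character(label))
  unknown <- unique(key[!key %in% names(band_map)])
  if (length(unknown) > 0) {
    stop(sprintf("unrecognized emotion label(s) %s; recognized labels are: %s",
                 paste0("'", unknown, "'", collapse = ", "),
                 paste(names(band_map), collapse = ", ")), call. = FALSE)
  }
  unname(band_map[key])
}

#' Score a phrase table on the tone channel
#'
#' Uses the `tone_code` column if the table already carries bands, otherwise
#' maps the `emotion` column through `band_map`.
#'
#' @param phrases Data frame with an `emotion` or `tone_code` column.
#' @param band_map Named integer map, see [map_emotion()].
#' @return The input as a tibble with an integer `tone_code` column.
#' @export
band_tone <- function(phrases, band_map = default_band_map()) {
  phrases <- tibble::as_tibble(phrases)
  if ("tone_code" %in% names(phrases)) {
    if (any(!phrases$tone_code %in% c(-1L, 0L, 1L))) {
      stop("tone_code values must be -1, 0 or +1", call. = FALSE)
    }
    phrases$tone_code <- as.integer(phrases$tone_code)
    return(phrases)
  }
  if (!"emotion" %in% names(phrases)) {
    stop("phrase table needs an 'emotion' or 'tone_code' column", call. = FALSE)
  }
  dplyr::mutate(phrases, tone_code = map_emotion(.data$emotion, band_map))
}
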