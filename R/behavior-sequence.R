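#' Behavior sequence
#'
#' A behavior sequence is an ordered run of categorical state labels, one per
#' 1-s bin, annotated with the label alphabet and a map assigning each label
#' to the `"social"` or `"nonsocial"` category. It is the substrate of all
#' Markov transition analysis.
#'
#' @param labels Character vector of state labels, one per bin (length >= 2).
#' @param alphabet Optional character vector giving the state order; defaults
#'   to the sorted unique labels.
#' @param category_map Named character vector mapping every label in the
#'   alphabet to `"social"` or `"nonsocial"`. Optional until
#'   [encode_two_state()] is called.
#' @param subject,session Optional identifiers carried through to outputs.
#'
#' @return An object of class `behavior_sequence`.
#' @seealso [fit_transitions()], [encode_two_state()], [default_category_map()]
#' @export
#' @examples
#' seq <- behavior_sequence(c("approach", "still", "rear", "approach"),
#'                          category_map = default_category_map())
#' encode_two_state(seq)
behavior_sequence <- function(labels, alphabet = NULL, category_map = NULL,
                              subject = NA_character_, session = NA_character_) {
  labels <- as.character(labels)
  if (length(labels) < 2L) {
    stop_sociodyn("a behavior sequence needs at least 2 bins, got ", length(labels))
  }
  if (anyNA(labels)) stop_sociodyn("behavior labels must not be NA")
  if (is.null(alphabet)) alphabet <- sort(unique(labels))
  missing_lab <- setdiff(labels, alphabet)
  if (length(missing_lab) > 0L) {
    stop_sociodyn("labels not in alphabet: ", paste(unique(missing_lab), collapse = ", "))
  }
  if (!is.null(category_map)) check_category_map(category_map, alphabet)
  structure(
    list(labels = labels, alphabet = alphabet, category_map = category_map,
         subject = subject, session = session),
    class = "behavior_sequence"
  )
}

check_category_map <- function(category_map, alphabet) {
  if (is.null(names(category_map))) {
    stop_sociodyn("category_map must be a named vector (label -> category)")
  }
  unmapped <- setdiff(alphabet, names(category_map))
  if (length(unmapped) > 0L) {
    stop_sociodyn("category_map is missing labels: ", paste(unmapped, collapse = ", "))
  }
  bad <- setdiff(unique(category_map[alphabet]), c("social", "nonsocial"))
  if (length(bad) > 0L) {
    stop_sociodyn("categories must be 'social' or 'nonsocial', got: ",
                  paste(bad, collapse = ", "))
  }
  invisible(category_map)
}

#' @export
print.behavior_sequence <- function(x, ...) {
  cat("<behavior_sequence> ", length(x$labels), " bins, ",
      length(x$alphabet), " states", sep = "")
  if (!is.na(x$subject)) cat(", subject ", x$subject, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.behavior_sequence <- function(x) length(x$labels)

#' Canonical social/nonsocial category map
#'
#' The 15-category ethogram of the juvenile-intruder assay: nine social
#' behaviors (reciprocated and non-reciprocated face sniff, flank sniff,
#' reciprocated and non-reciprocated anogenital sniff, close follow, approach,
#' dominant climb, attack) and six nonsocial behaviors (groom, dig, rear,
#' climb, still, ambulate). Short aliases `face_sniff` and `anogenital_sniff`
#' are included for convenience.
#'
#' @return Named character vector, label -> `"social"`/`"nonsocial"`.
#' @export
default_category_map <- function() {
  c(face_sniff_recip = "social", face_sniff_nonrecip = "social",
    flank_sniff = "social",
    anogenital_sniff_recip = "social", anogenital_sniff_nonrecip = "social",
    close_follow = "social", approach = "social",
    dominant_climb = "social", attack = "social",
    face_sniff = "social", anogenital_sniff = "social",
    groom = "nonsocial", dig = "nonsocial", rear = "nonsocial",
    climb = "nonsocial", still = "nonsocial", ambulate = "nonsocial")
}

#' Collapse a behavior sequence to the two-state social/nonsocial alphabet
#'
#' Maps every label through the sequence's category map (or one supplied
#' here), yielding a sequence over the alphabet `{social, nonsocial}`. This is
#' the two-state Markov encoding used for within-/across-state transition
#' analysis.
#'
#' @param seq A [behavior_sequence()].
#' @param category_map Optional named vector overriding `seq$category_map`.
#'
#' @return A `behavior_sequence` over `c("social", "nonsocial")`.
#' @export
encode_two_state <- function(seq, category_map = NULL) {
  stopifnot(inherits(seq, "behavior_sequence"))
  map <- category_map %||% seq$category_map
  if (is.null(map)) stop_sociodyn("no category_map available for this sequence")
  check_category_map(map, seq$alphabet)
  behavior_sequence(unname(map[seq$labels]),
                    alphabet = c("social", "nonsocial"),
                    category_map = c(social = "social", nonsocial = "nonsocial"),
                    subject = seq$subject, session = seq$session)
}

#' Resolve multi-label bins to a single label
#'
#' Manual annotation may assign several simultaneous codes to one 1-s bin.
#' Each bin is resolved to a single label by category priority (default:
#' social codes win over nonsocial ones, reflecting a social-engagement
#' focus); ties within a category keep the first-listed label.
#'
#' @param bins A list of character vectors, one vector of labels per bin.
#' @param category_map Named label -> category vector.
#' @param priority Character vector of categories, highest priority first.
#'
#' @return Character vector with one label per bin.
#' @export
resolve_multilabel <- function(bins, category_map,
                               priority = c("social", "nonsocial")) {
  stopifnot(is.list(bins))
  vapply(bins, function(labs) {
    labs <- as.character(labs)
    if (length(labs) == 0L) stop_sociodyn("empty bin: no label to resolve")
    if (length(labs) == 1L) return(labs)
    cats <- category_map[labs]
    ranks <- match(cats, priority)
    if (anyNA(ranks)) {
      stop_sociodyn("label(s) with no category in priority list: ",
                    paste(labs[is.na(ranks)], collapse = ", "))
    }
    labs[which.min(ranks)]
  }, character(1))
}

#' Build behavior sequences from a long table
#'
#' Converts a table with one row per (subject, session, bin) into a list of
#' [behavior_sequence()] objects, one per subject x session, ordered by
#' `bin_index`.
#'
#' @param data Data frame with columns `subject`, `session`, `bin_index`,
#'   `state_label`.
#' @param category_map Optional named label -> category vector attached to
#'   every sequence.
#'
#' @return Named list of `behavior_sequence` objects
#'   (`"<subject>.<session>"`).
#' @export
as_behavior_sequences <- function(data, category_map = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("subject", "session", "bin_index", "state_label")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop_sociodyn("missing columns: ", paste(miss, collapse = ", "))
  }
  data |>
    dplyr::arrange(.data$subject, .data$session, .data$bin_index) |>
    dplyr::group_by(.data$subject, .data$session) |>
    dplyr::group_map(~ behavior_sequence(
      .x$state_label,
      category_map = category_map,
      subject = .y$subject, session = .y$session
    )) |>
    stats::setNames(
      data |>
        dplyr::distinct(.data$subject, .data$session) |>
        dplyr::arrange(.data$subject, .data$session) |>
        (\(d) paste(d$subject, d$session, sep = "."))()
    )
}
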