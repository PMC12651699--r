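#' The FDI two-digit tooth code system
#'
#' The FDI (Federation Dentaire Internationale) system identifies each of the
#' 32 permanent teeth by a two-digit code. The first digit is the quadrant of
#' the dental arch (1 upper right, 2 upper left, 3 lower left, 4 lower right,
#' from the viewpoint facing the patient) and the second digit is the tooth
#' position within the quadrant, counted outward from the central incisor (1)
#' to the third molar (8). Quadrants 1-2 form the upper arch, 3-4 the lower
#' arch.
#'
#' `parse_fdi()` decomposes two-digit codes (given as integers or two-character
#' strings) into quadrant and position, rejecting anything outside the 32
#' valid permanent-tooth codes with an error of class
#' `dentalign_invalid_code`.
#'
#' @param code Vector of FDI codes, integer (e.g. `11`) or character
#'   (e.g. `"11"`).
#' @return A tibble with one row per input code and columns `code` (integer),
#'   `quadrant`, `position`, and `arch` (`"upper"` or `"lower"`).
#' @examples
#' parse_fdi(c(11, 48))
#' parse_fdi("25")
#' @export
parse_fdi <- function(code) {
  code_int <- suppressWarnings(as.integer(code))
  bad <- is.na(code_int) | !(code_int %in% fdi_all_codes())
  if (any(bad)) {
    rlang::abort(
      paste0(
        "Invalid FDI code(s): ",
        paste(unique(code[bad]), collapse = ", "),
        ". Valid permanent-tooth codes are 11-18, 21-28, 31-38, 41-48."
      ),
      class = c("dentalign_invalid_code", "dentalign_error")
    )
  }
  quadrant <- code_int %/% 10L
  tibble::tibble(
    code = code_int,
    quadrant = quadrant,
    position = code_int %% 10L,
    arch = ifelse(quadrant <= 2L, "upper", "lower")
  )
}

#' All 32 valid permanent-tooth FDI codes
#' @return Integer vector of the 32 codes, in linear arch-index order
#'   (see [fdi_to_linear()]).
#' @export
fdi_all_codes <- function() {
  c(18:11, 21:28, 48:41, 31:38)
}

#' Convert between FDI codes and the linear arch index
#'
#' The linear arch index places every permanent tooth on a single 1..32 axis
#' ordered viewer-left to viewer-right on a standard dental chart (facing the
#' patient): upper arch 18..11 then 21..28 maps to 1..16, lower arch 48..41
#' then 31..38 maps to 17..32. Physically adjacent teeth — including the
#' midline pairs 11/21 and 41/31 — get consecutive indices, which is what
#' makes both the spatial soft label and the sliding-template correction
#' meaningful. Index 0 is reserved for the missing-tooth placeholder and has
#' no FDI code.
#'
#' @param code Vector of FDI codes (integer or character).
#' @param idx Vector of linear indices in 1..32.
#' @return `fdi_to_linear()`: integer vector of linear indices in 1..32.
#'   `linear_to_fdi()`: integer vector of two-digit FDI codes.
#' @examples
#' fdi_to_linear(c(18, 11, 21, 28)) # 1, 8, 9, 16
#' linear_to_fdi(17)                # 48
#' @export
fdi_to_linear <- function(code) {
  p <- parse_fdi(code)
  idx <- integer(nrow(p))
  q <- p$quadrant
  idx[q == 1L] <- 9L - p$position[q == 1L]
  idx[q == 2L] <- 8L + p$position[q == 2L]
  idx[q == 4L] <- 25L - p$position[q == 4L]
  idx[q == 3L] <- 24L + p$position[q == 3L]
  idx
}

#' @rdname fdi_to_linear
#' @export
linear_to_fdi <- function(idx) {
  idx <- as.integer(idx)
  if (any(is.na(idx)) || any(idx < 0L | idx > 32L)) {
    rlang::abort("Linear index must be in 0..32.", class = c("dentalign_invalid_code", "dentalign_error"))
  }
  if (any(idx == 0L)) {
    rlang::abort(
      "Linear index 0 is the missing-tooth placeholder and has no FDI code.",
      class = c("dentalign_placeholder_index", "dentalign_error")
    )
  }
  code <- integer(length(idx))
  u1 <- idx <= 8L
  u2 <- idx > 8L & idx <= 16L
  l4 <- idx > 16L & idx <= 24L
  l3 <- idx > 24L
  code[u1] <- 10L + (9L - idx[u1])
  code[u2] <- 20L + (idx[u2] - 8L)
  code[l4] <- 40L + (25L - idx[l4])
  code[l3] <- 30L + (idx[l3] - 24L)
  code
}

#' Arch membership of a linear index
#' @param idx Vector of linear indices in 1..32.
#' @return Character vector, `"upper"` (1..16) or `"lower"` (17..32).
#' @export
arch_of <- function(idx) {
  idx <- as.integer(idx)
  check_no_placeholder(idx)
  ifelse(idx <= 16L, "upper", "lower")
}

check_no_placeholder <- function(idx) {
  if (any(is.na(idx)) || any(idx < 1L | idx > 32L)) {
    rlang::abort(
      "Linear index must be in 1..32; 0 (the missing-tooth placeholder) takes part in sequences only.",
      class = c("dentalign_placeholder_index", "dentalign_error")
    )
  }
  invisible(idx)
}

#' Spatial distance between two teeth along the arch
#'
#' Distance is counted in tooth steps along the linear arch axis: `|a - b|`
#' when both teeth lie on the same arch. Teeth on different arches are not
#' spatial neighbours in any sense the soft label should honour, so the
#' cross-arch distance is `Inf` (a sentinel, deliberately not a large finite
#' number: the default soft label then gives the other arch exactly zero
#' mass).
#'
#' @param a,b Vectors of linear indices in 1..32 (recycled to common length).
#' @return Numeric vector: non-negative integer distances, `Inf` across
#'   arches.
#' @examples
#' arch_distance(fdi_to_linear(11), fdi_to_linear(21)) # 1: midline neighbours
#' arch_distance(fdi_to_linear(11), fdi_to_linear(41)) # Inf: different arches
#' @export
arch_distance <- function(a, b) {
  a <- as.integer(a)
  b <- as.integer(b)
  check_no_placeholder(a)
  check_no_placeholder(b)
  same <- (a <= 16L) == (b <= 16L)
  ifelse(same, abs(a - b), Inf)
}

#' Anatomical tooth class of an FDI code
#'
#' The within-quadrant position determines the tooth type: positions 1-2 are
#' incisors, 3 the canine, 4-5 premolars, 6-8 molars.
#'
#' @param code Vector of FDI codes (integer or character).
#' @return Character vector with values `"incisor"`, `"canine"`,
#'   `"premolar"`, `"molar"`.
#' @examples
#' tooth_class_of(c(13, 45, 37)) # canine, premolar, molar
#' @export
tooth_class_of <- function(code) {
  p <- parse_fdi(code)
  cut_pts <- c("incisor", "incisor", "canine", "premolar", "premolar",
               "molar", "molar", "molar")
  cut_pts[p$position]
}

#' Ideal arch templates
#'
#' The sequence-correction algorithm slides the detected label sequence along
#' the ideal consecutive numbering of one arch: the upper template is the
#' linear run 1..16, the lower template 17..32.
#'
#' @param arch `"upper"` or `"lower"`.
#' @return An object of class `arch_template`: a list with `arch` and the
#'   integer `sequence`.
#' @examples
#' arch_template("upper")$sequence # 1:16
#' @export
arch_template <- function(arch = c("upper", "lower")) {
  arch <- match.arg(arch)
  structure(
    list(
      arch = arch,
      sequence = if (arch == "upper") 1:16 else 17:32
    ),
    class = "arch_template"
  )
}

#' @export
print.arch_template <- function(x, ...) {
  cat("<arch_template> ", x$arch, " arch: ",
      paste(x$sequence, collapse = " "), "\n", sep = "")
  invisible(x)
}
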