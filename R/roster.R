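#' Node roster for the biomedical-prevention attitude network
#'
#' A roster describes the nodes entering the network: a short code, the
#' conditional family used for that node (\code{"gaussian"} or
#' \code{"binary"}), and for gaussian belief items the admissible scale range
#' (Likert 1-7; age is an open-scale standardized gaussian node).
#'
#' @param code character vector of unique node codes.
#' @param family character vector, \code{"gaussian"} or \code{"binary"}.
#' @param lower,upper numeric scale bounds for gaussian nodes (\code{NA} for
#'   unbounded nodes and for binary nodes).
#' @param description free-text node label.
#' @return A \code{node_roster}: a data frame with columns \code{code},
#'   \code{family}, \code{lower}, \code{upper}, \code{description}.
#' @export
node_roster <- function(code, family, lower = NA_real_, upper = NA_real_,
                        description = code) {
  code <- as.character(code)
  family <- rep_len(as.character(family), length(code))
  if (anyDuplicated(code)) stop("node codes must be unique")
  if (!all(family %in% c("gaussian", "binary"))) {
    stop("family must be 'gaussian' or 'binary'")
  }
  lower <- rep_len(as.numeric(lower), length(code))
  upper <- rep_len(as.numeric(upper), length(code))
  description <- rep_len(as.character(description), length(code))
  if (any(family == "binary" & (!is.na(lower) | !is.na(upper)))) {
    stop("binary nodes have no scale range")
  }
  out <- data.frame(code = code, family = family, lower = lower,
                    upper = upper, description = description,
                    stringsAsFactors = FALSE)
  class(out) <- c("node_roster", "data.frame")
  out
}

#' Default 35-node roster: uptake, demographics, and belief items
#'
#' Three binary behaviour nodes (PrEP use, viral-load sorting, steady
#' partner), a standardized continuous age node, an HIV-risk-perception
#' composite, 21 PrEP-belief items and 9 VLS-belief items on 1-7 Likert
#' scales.
#'
#' @return A \code{\link{node_roster}} with 35 rows (3 binary, 32 gaussian).
#' @examples
#' r <- make_default_roster()
#' table(r$family)
#' @export
make_default_roster <- function() {
  prep_desc <- c(
    "Impact quality of sex life", "Impact on serodiscordant couples",
    "Solidarity towards HIV-positive individuals", "Efficacy",
    "Essential for high-risk", "Redundant", "Affordability",
    "Expectation HIV drug resistance", "Burden side-effects",
    "Burden PrEP procedures", "Impact on sex life",
    "Opinion relevant others PrEP use", "Gay friends use PrEP",
    "Opinion gay friends PrEP use", "PrEP associated with high-risk",
    "PrEP associated with sexual health",
    "PrEP associated with better sex life",
    "PrEP associated with promiscuity", "Easier to use than condoms",
    "Self-efficacy daily PrEP", "Self-efficacy event-driven PrEP")
  vls_desc <- c(
    "Prevents HIV transmission", "Protects serodiscordant couples",
    "Efficacy", "Easier to use than condoms", "Impact quality sex life",
    "Opinion others VLS use", "Gay friends use VLS",
    "Opinion gay friends VLS use", "Self-efficacy VLS")
  rbind(
    node_roster(c("PrEP", "VLS", "sp"), "binary",
                description = c("PrEP use past 6 months",
                                "Viral load sorting past 6 months",
                                "Steady partner past 6 months")),
    node_roster("age", "gaussian", description = "Age (standardized)"),
    node_roster("riskHIV", "gaussian", 1, 7, "HIV risk perception"),
    node_roster(paste0("prep", 1:21), "gaussian", 1, 7, prep_desc),
    node_roster(paste0("vls", 1:9), "gaussian", 1, 7, vls_desc)
  )
}

#' @export
#' @method print node_roster
print.node_roster <- function(x, ...) {
  cat("Node roster:", nrow(x), "nodes (",
      sum(x$family == "binary"), "binary,",
      sum(x$family == "gaussian"), "gaussian )\n")
  print.data.frame(head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more nodes\n")
  invisible(x)
}

gaussian_codes <- function(roster) roster$code[roster$family == "gaussian"]
binary_codes <- function(roster) roster$code[roster$family == "binary"]

#' Write / read a roster as JSON
#'
#' @param roster a \code{\link{node_roster}}.
#' @param path file path.
#' @return \code{read_roster} returns a \code{node_roster}.
#' @export
write_roster <- function(roster, path) {
  jsonlite::write_json(as.data.frame(roster), path, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$lower)) x$lower <- NA_real_
  if (is.null(x$upper)) x$upper <- NA_real_
  x$lower[x$family == "binary"] <- NA_real_
  x$upper[x$family == "binary"] <- NA_real_
  node_roster(x$code, x$family, x$lower, x$upper, x$description)
}
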