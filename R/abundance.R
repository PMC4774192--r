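#' Relative maximal enzyme activities across physiological states
#'
#' Returns the table of enzyme abundance ratios used to scale maximal
#' enzyme activities (Vmax) between physiological states of the rat liver.
#' All ratios are relative to the fed state (the reference, alpha = 1).
#' Where a literature range is reported it is given as \code{*_min}/\code{*_max};
#' enzymes with no reported range use the fixed mean. The normal-liver column
#' corresponds to the geometric mean of the fed and fasted ratios.
#'
#' Enzymes of the network that do not appear in this table keep alpha = 1 in
#' every state.
#'
#' @return A data.frame with columns \code{enzyme}, \code{normal},
#'   \code{fasted}, \code{fasted_min}, \code{fasted_max}, \code{diabetic},
#'   \code{diabetic_min}, \code{diabetic_max}. Range columns are \code{NA}
#'   when no range is reported.
#' @export
#' @examples
#' tab <- abundance_table()
#' tab[tab$enzyme == "GK", ]
abundance_table <- function() {
  data.frame(
    enzyme       = c("FBP1", "FBP2", "GK",  "GlcT", "GP",  "G6P", "GS",
                     "PC",   "PEPCK", "PFK1", "PFK2", "PK"),
    normal       = c(1.00, 0.66, 0.48, 1.00, 0.89, 1.41, 1.00,
                     1.25, 1.41, 0.76, 0.66, 0.58),
    fasted       = c(1.00, 0.43, 0.23, 1.00, 0.80, 2.00, 1.00,
                     1.56, 2.00, 0.57, 0.43, 0.33),
    fasted_min   = c(NA,   0.40, 0.12, NA,   0.65, NA,   NA,
                     NA,   NA,   0.30, 0.40, 0.25),
    fasted_max   = c(NA,   0.475, 0.46, NA,  1.00, NA,   NA,
                     NA,   NA,   0.85, 0.475, 0.50),
    diabetic     = c(4.00, 0.26, 0.24, 1.35, 0.45, 3.54, 1.70,
                     3.75, 4.24, 0.30, 0.26, 0.29),
    diabetic_min = c(NA,   0.20, 0.19, 1.00, 0.40, 1.48, 1.24,
                     2.50, 2.83, 0.23, 0.20, 0.17),
    diabetic_max = c(NA,   0.40, 0.33, 2.00, 0.63, 7.07, 2.25,
                     5.00, 5.66, 0.41, 0.40, 0.52),
    stringsAsFactors = FALSE
  )
}

#' Physiological states recognised by the model
#' @return Character vector of state labels.
#' @export
physiological_states <- function() c("fed", "normal", "fasted", "diabetic")

#' Abundance scaling factor for one enzyme in one state
#'
#' @param enzyme Enzyme/transporter id (Table row name, e.g. "GK").
#' @param state One of \code{physiological_states()}.
#' @param abundance Abundance table, see [abundance_table()].
#' @param quiet Suppress the notice emitted when the enzyme is absent from the
#'   table (in which case alpha = 1).
#' @return The scalar ratio alpha = <E>_state / <E>_fed.
#' @export
abundance_ratio <- function(enzyme, state, abundance = abundance_table(),
                            quiet = FALSE) {
  state <- match.arg(state, physiological_states())
  if (state == "fed") return(1)
  i <- match(enzyme, abundance$enzyme)
  if (is.na(i)) {
    if (!quiet)
      message("enzyme '", enzyme,
              "' has no abundance entry; using alpha = 1 in state '", state, "'")
    return(1)
  }
  abundance[[state]][i]
}

#' Scale a reference maximal rate to a physiological state
#'
#' The maximal rate of an enzyme in a non-reference state is the fed-state
#' reference value multiplied by the ratio of mean enzyme abundances,
#' \code{alpha_state = <E>_state / <E>_fed}. The fed state is the reference
#' (alpha = 1). A caller-supplied \code{alpha} (e.g. a sample drawn within
#' the reported range) overrides the table mean.
#'
#' @param enzyme Enzyme id.
#' @param state Physiological state.
#' @param vmax_fed Reference maximal rate in the fed state (umol/g/h).
#' @param abundance Abundance table.
#' @param alpha Optional explicit scaling factor overriding the table mean.
#' @param quiet Passed to [abundance_ratio()].
#' @return Scaled maximal rate alpha * vmax_fed.
#' @export
#' @examples
#' scale_vmax("GK", "fasted", vmax_fed = 100)   # 0.23 * 100
scale_vmax <- function(enzyme, state, vmax_fed = 1,
                       abundance = abundance_table(), alpha = NULL,
                       quiet = FALSE) {
  stopifnot(is.numeric(vmax_fed), vmax_fed >= 0)
  if (is.null(alpha))
    alpha <- abundance_ratio(enzyme, state, abundance, quiet = quiet)
  stopifnot(alpha > 0)
  alpha * vmax_fed
}

#' Vector of abundance scaling factors for every reaction of a network
#'
#' @param network A [build_network()] object.
#' @param state Physiological state.
#' @param abundance Abundance table.
#' @param sample Optional named vector of sampled ratios (e.g. from
#'   [sample_abundance_ratios()]); entries present override the table means.
#' @return Named numeric vector over the network's reaction ids.
#' @export
alpha_vector <- function(network, state, abundance = abundance_table(),
                         sample = NULL) {
  state <- match.arg(state, physiological_states())
  ids <- names(network$reactions)
  a <- setNames(rep(1, length(ids)), ids)
  if (state != "fed") {
    for (id in ids) {
      key <- alpha_key(id)
      j <- match(key, abundance$enzyme)
      if (!is.na(j)) a[id] <- abundance[[state]][j]
    }
  }
  if (!is.null(sample)) {
    for (key in names(sample)) {
      hit <- vapply(ids, function(id) identical(alpha_key(id), key), logical(1))
      a[hit] <- sample[[key]]
    }
  }
  a
}

# Table-1 key for a reaction id: mitochondrial PEPCK shares the PEPCK entry.
alpha_key <- function(reaction_id) {
  if (reaction_id == "PEPCK_mito") return("PEPCK")
  reaction_id
}
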