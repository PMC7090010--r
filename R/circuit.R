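#' Define an intein-split transcription-factor AND gate
#'
#' Each gate holds a transcription factor (e.g. a minimal ECF sigma
#' factor) split at its linker and fused to the two halves of a split
#' intein. One input drives expression of the N-half chimera, another the
#' C-half chimera; only when both are present can the intein splice the
#' factor back together and activate the gate's output reporter -- an AND
#' gate.
#'
#' @param gate_id Gate identifier.
#' @param n_half_driver,c_half_driver Input names driving the N- and
#'   C-half chimeras; must differ.
#' @param output_reporter Reporter the reconstituted factor activates.
#' @param tf,intein Optional transcription-factor and intein labels.
#' @return One-row gate tibble.
#' @export
gate_spec <- function(gate_id, n_half_driver, c_half_driver, output_reporter,
                      tf = NA_character_, intein = NA_character_) {
  if (n_half_driver == c_half_driver) {
    abort(
      "a two-input gate needs two distinct drivers",
      class = "inteinscreen_format_error"
    )
  }
  tibble(
    gate_id = gate_id, tf = tf, intein = intein,
    n_half_driver = n_half_driver, c_half_driver = c_half_driver,
    output_reporter = output_reporter
  )
}

#' Assemble a logic circuit from gates
#'
#' @param inputs Declared input names.
#' @param gates Tibble of [gate_spec()] rows.
#' @return An object of class `logic_circuit`.
#' @export
circuit_spec <- function(inputs, gates) {
  drivers <- unique(c(gates$n_half_driver, gates$c_half_driver))
  undeclared <- setdiff(drivers, inputs)
  if (length(undeclared) > 0) {
    abort(
      paste0("gate driver(s) not declared as inputs: ", paste(undeclared, collapse = ", ")),
      class = "inteinscreen_format_error"
    )
  }
  structure(
    list(
      inputs = inputs,
      gates = as_tibble(gates),
      reporters = unique(gates$output_reporter)
    ),
    class = "logic_circuit"
  )
}

#' @export
print.logic_circuit <- function(x, ...) {
  cat(
    "<logic_circuit> ", length(x$inputs), " input(s), ", nrow(x$gates),
    " gate(s), ", length(x$reporters), " reporter(s)\n",
    sep = ""
  )
  print(x$gates)
  invisible(x)
}

#' Evaluate a single AND gate
#'
#' @param gate One-row gate tibble ([gate_spec()]).
#' @param state Named logical vector of input states covering both drivers.
#' @return Logical: gate output.
#' @export
evaluate_gate <- function(gate, state) {
  needed <- c(gate$n_half_driver, gate$c_half_driver)
  missing_in <- setdiff(needed, names(state))
  if (length(missing_in) > 0) {
    abort(
      paste0("state missing input(s): ", paste(missing_in, collapse = ", ")),
      class = "inteinscreen_state_error"
    )
  }
  unname(state[gate$n_half_driver] & state[gate$c_half_driver])
}

#' Enumerate the full truth table of a circuit
#'
#' All 2^n input combinations are enumerated in binary order (first input
#' is the most significant bit); each reporter reads the OR over the gates
#' that drive it.
#'
#' @param circuit A [circuit_spec()].
#' @return Tibble with one row per input combination: one logical column
#'   per input, one per reporter, and `n_on` (reporters on in that row).
#' @export
truth_table <- function(circuit) {
  ni <- length(circuit$inputs)
  if (ni > 16) {
    abort("at most 16 inputs supported", class = "inteinscreen_size_error")
  }
  states <- tidyr::expand_grid(!!!setNames(
    rep(list(c(FALSE, TRUE)), ni),
    circuit$inputs
  ))
  rows <- pmap(states, function(...) {
    state <- unlist(list(...))
    outs <- map_lgl(
      setNames(circuit$reporters, circuit$reporters),
      function(rep_name) {
        g <- circuit$gates |> filter(.data$output_reporter == rep_name)
        any(map_lgl(seq_len(nrow(g)), function(i) evaluate_gate(g[i, ], state)))
      }
    )
    as_tibble(as.list(outs))
  }) |> list_rbind()
  bind_cols(states, rows) |>
    mutate(n_on = rowSums(across(all_of(circuit$reporters))))
}

#' The three-input, three-output intein logic circuit
#'
#' Three AND gates over the inducer inputs arabinose, rhamnose and AHL:
#' the blue reporter (mTagBFP) fires on rhamnose AND AHL, green (GFP) on
#' arabinose AND rhamnose, red (mCherry) on arabinose AND AHL. Any two
#' inputs light exactly one reporter, all three light all reporters, and
#' one or zero inputs light none -- 4 of the 8 input combinations produce
#' output.
#'
#' @return A [circuit_spec()].
#' @export
circuit_three_input <- function() {
  circuit_spec(
    inputs = c("ara", "rha", "AHL"),
    gates = bind_rows(
      gate_spec("gate_blue", "rha", "AHL", "mTagBFP", tf = "ECF17mut", intein = "NrdJ-1"),
      gate_spec("gate_green", "ara", "rha", "GFP", tf = "ECF20mut", intein = "M86"),
      gate_spec("gate_red", "ara", "AHL", "mCherry", tf = "ECF16mut", intein = "SspGyrB")
    )
  )
}
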