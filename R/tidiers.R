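# broom-style tidiers for fitted objects and reports.

#' Tidy an LVQ model
#'
#' One row per prototype: its class, win count and waveform (as a
#' list-column), matching the competitive-layer state after training or
#' pruning.
#'
#' @param x An `lvq_model`.
#' @param ... Unused.
#' @return A tibble with columns `prototype`, `class`, `win_count`,
#'   `weights`.
#' @method tidy lvq_model
#' @export
tidy.lvq_model <- function(x, ...) {
  tibble::tibble(
    prototype = seq_len(nrow(x$prototypes)),
    class = x$classes[x$proto_class],
    win_count = x$win_counts,
    weights = lapply(seq_len(nrow(x$prototypes)),
                     function(i) x$prototypes[i, ])
  )
}

#' @rdname tidy.lvq_model
#' @method glance lvq_model
#' @export
glance.lvq_model <- function(x, ...) {
  tibble::tibble(
    hn = nrow(x$prototypes),
    n_inputs = x$n_inputs,
    n_classes = x$n_classes,
    alpha = x$alpha,
    epochs_run = x$epochs_run,
    trained = x$trained,
    final_error_pct = if (x$trained) utils::tail(x$history$error_pct, 1) else NA_real_
  )
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report` from [run_experiment()].
#' @param ... Unused.
#' @return Per-subject rows ([tidy()]) or a one-row summary ([glance()])
#'   with mean error/accuracy, FAR, FRR and EER.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::mutate(x$rows, design = x$design, classifier = x$classifier,
                .before = 1)
}

#' @rdname tidy.eval_report
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    design = x$design,
    classifier = x$classifier,
    n_subjects = nrow(x$rows),
    mean_error_pct = x$mean_error_pct,
    mean_accuracy_pct = x$mean_accuracy_pct,
    far = x$rates$far,
    frr = x$rates$frr,
    eer = x$eer,
    seed = x$seed
  )
}
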