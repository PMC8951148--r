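#' Predict from a trained inverse solver
#'
#' A pure function of the model and the input: repeated calls give identical
#' output, and batch prediction equals per-item prediction stacked.
#'
#' @param object An `epimap_model`.
#' @param newdata For `fcn`: a samples x torso-leads matrix. For `lstm`: one
#'   torso sequence (time x leads matrix). For `cnn`: an image array
#'   `(height, width, n_frames)` or a single image matrix.
#' @param ... Unused.
#' @return Predicted epicardial potentials: a samples/time x output matrix.
#' @export
predict.epimap_model <- function(object, newdata, ...) {
  switch(object$spec$kind,
    fcn = predict_fcn(object, newdata),
    lstm = predict_lstm(object, newdata),
    cnn = predict_cnn(object, newdata)
  )
}
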