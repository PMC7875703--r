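# Shared fixture builders; everything is generated in code at test time.

# internal autodiff/forward machinery exercised directly by the tests
tp_new <- edembed:::tp_new
tp_val <- edembed:::tp_val
tp_const <- edembed:::tp_const
tp_param <- edembed:::tp_param
tp_mm <- edembed:::tp_mm
tp_add <- edembed:::tp_add
tp_addrow <- edembed:::tp_addrow
tp_mul <- edembed:::tp_mul
tp_smul <- edembed:::tp_smul
tp_t <- edembed:::tp_t
tp_tanh <- edembed:::tp_tanh
tp_gelu <- edembed:::tp_gelu
tp_rows <- edembed:::tp_rows
tp_rbind <- edembed:::tp_rbind
tp_tile <- edembed:::tp_tile
tp_mean <- edembed:::tp_mean
tp_layernorm <- edembed:::tp_layernorm
tp_mha <- edembed:::tp_mha
tp_rownorm <- edembed:::tp_rownorm
tp_xent_rows <- edembed:::tp_xent_rows
tp_bce_logits <- edembed:::tp_bce_logits
tp_grads_for <- edembed:::tp_grads_for
ed_init_params <- edembed:::ed_init_params
`%||%` <- edembed:::`%||%`

mk_visits <- function(n = 4L, cc = NULL, ...) {
  visit_table(visit_id = sprintf("t%03d", seq_len(n)),
              chief_complaint = cc %||% rep("chest pain", n),
              triage_time = rep("2016-01-10T08:00:00", n),
              ...)
}

mk_stats <- function() {
  data.frame(field = vital_fields(),
             mean = c(43.7, 0.505, 135.4, 78.3, 95.8, 97.2, 19.5, 37.1,
                      152.8, 52.5, 2.7, 14.7, 4.0, 4.9, 5.9),
             sd = c(26.9, 0.5, 27.3, 15.8, 25.6, 3.64, 3.4, 1.0,
                    26.6, 22.8, 3.2, 1.4, 0.3, 0.6, 0.5))
}

tiny_cfg <- function(...) {
  args <- list(d_hidden = 8L, n_layers = 1L, n_heads = 2L, d_text = 12L,
               d_ff = 16L, dropout = 0)
  do.call(ed_config, utils::modifyList(args, list(...)))
}

small_cfg <- function(...) ed_config(preset = "small", d_text = 64L, ...)

rand_inputs <- function(cfg, B = 3L, seed = 1L) {
  set.seed(seed)
  list(S = matrix(stats::rnorm(B * 15), B),
       CC = matrix(stats::rnorm(B * cfg$d_text), B),
       HX = matrix(stats::rnorm(B * cfg$d_text), B),
       hx = rep(1, B))
}

# direct embedding via the internal forward (constants, no dropout)
fwd_eps <- function(params, cfg, inp) {
  tp <- tp_new(1024L)
  pid <- lapply(params, function(x) tp_const(tp, x))
  e <- edembed:::.tp_encoder(tp, pid, cfg, inp$S, inp$CC, inp$HX, inp$hx)
  tp_val(tp, e$eps)
}
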