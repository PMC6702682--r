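# Published staged-fit composition template: fitting-point count, class
# composition and optimizer per reparametrization stage (6D HONO study).
# Shipped as a template; actual stage sizes are fully configurable.
n_points	classes	optimization
53	core	Global/Local
367	1D + core	Local
546	1D + 2D + core	Local
648	1D + 2D + rnd(6D) + core	Local
954	1D + 2D + rnd(6D) + LIIC-IRC + core	Local
1084	1D + 2D + rnd(6D) + LIIC-IRC + rnd(LIIC) + core	Local
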