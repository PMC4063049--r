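# Default two-slice fall-risk network.
#
# Nodes: FA (hidden fall-risk) plus six observable evidence channels:
#   Sl sleeping, Sh showering, C cooking, TV television, Tr training,
#   FE wearable fall event.
# CPT values are flat vectors in column-major order with the child as the
# last dimension; states are 1 = false, 2 = true. "prev:X" marks a parent
# taken from the previous time slice.
#
# The slice-1 tables for Sl and TV and the slice-2 tables for Sh and C are
# the published reference tables, transcribed verbatim (the Sh table does
# not normalize in two columns; the loader repairs it by complementing the
# child=false entry and warns). Every other table is a package default:
# a 0.2 fall-risk prior, a strongly self-inhibiting FA transition
# (consecutive falls are improbable), a detector channel FE with 0.9
# sensitivity / 0.05 false-alarm rate, elevated fall likelihood while
# training, and Sh/C slice-1 columns taken from the Tr_prev=false columns
# of their slice-2 tables.
nodes:
- name: FA
  role: hidden
- name: Sl
  role: observable
- name: Sh
  role: observable
- name: C
  role: observable
- name: TV
  role: observable
- name: Tr
  role: observable
- name: FE
  role: observable
intra_edges:
- [FA, Sl]
- [FA, Sh]
- [FA, C]
- [FA, TV]
- [FA, Tr]
- [FA, FE]
inter_edges:
- [FA, FA]
- [Sh, Sl]
- [Tr, Sh]
- [Tr, C]
cpts:
  slice1:
    FA:
      parents: []
      values: [0.8, 0.2]
    Sl:                      # published: P(Sl=t|FA=f)=0.6, P(Sl=t|FA=t)=0.1
      parents: [FA]
      values: [0.4, 0.9, 0.6, 0.1]
    TV:                      # published: P(TV=t|FA=f)=0.5, P(TV=t|FA=t)=0.13
      parents: [FA]
      values: [0.5, 0.87, 0.5, 0.13]
    Sh:
      parents: [FA]
      values: [0.9, 0.9, 0.1, 0.1]
    C:
      parents: [FA]
      values: [0.6, 0.6, 0.4, 0.4]
    Tr:
      parents: [FA]
      values: [0.8, 0.3, 0.2, 0.7]
    FE:
      parents: [FA]
      values: [0.95, 0.1, 0.05, 0.9]
  slice2:
    FA:                      # P(FA=t|prev f)=0.1, P(FA=t|prev t)=0.05
      parents: [prev:FA]
      values: [0.9, 0.95, 0.1, 0.05]
    Sl:                      # sleep more likely right after a shower
      parents: [prev:Sh, FA]
      values: [0.4, 0.2, 0.9, 0.9, 0.6, 0.8, 0.1, 0.1]
    Sh:                      # published (two columns do not normalize)
      parents: [prev:Tr, FA]
      values: [0.9, 0.2, 0.9, 0.5, 0.5, 0.8, 0.1, 0.1]
    C:                       # published
      parents: [prev:Tr, FA]
      values: [0.6, 0.2, 0.6, 0.6, 0.4, 0.8, 0.4, 0.4]
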