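"index","length_m","diameter_m","leaf_count","mass_kg","leaf_mass_kg"
1,0.0627510588371781,0.00237825717948149,2,0.000284050785430709,0.000336587917405394
2,0.059544096701968,0.00222773511202469,2,0.000234904469146828,0.000252633434315517
3,0.0639344821868823,0.00206605645181539,2,0.000228550968591099,0.000181773612999364
4,0.0582251319374355,0.00204510354273415,2,0.000179097041140928,0.000125648332850199
5,0.0597935556487637,0.00175818080621635,2,0.000158042473901584,8.48582151796662e-05
6,0.0616444423264684,0.00169145961112518,2,0.00013601974194928,5.92256219054634e-05
7,0.0555677704291244,0.00163250008929045,2,0.000107666444287358,4.30081186199467e-05
8,0.0590405409554896,0.00147333372218568,2,9.69476975865029e-05,3.34939366717704e-05
9,0.0597664109039999,0.00134997622540973,2,7.97232572725524e-05,2.31406342708051e-05
10,0.0595983962868872,0.00125000523121023,2,7.00833622267717e-05,1.6644264769052e-05
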