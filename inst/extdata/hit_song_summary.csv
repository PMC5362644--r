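rank,title,artist,length_s,pct_usable,n_usable
1,Uptown Funk!,Mark Ronson Feat. Bruno Mars,270,98.57,13855245
2,Thinking Out Loud,Ed Sheeran,282,98.97,17142656
3,See You Again,Wiz Khalifa Feat. Charlie Puth,230,98.73,12522399
4,Trap Queen,Fetty Wap,223,98.77,6072939
5,Sugar,Maroon 5,236,98.92,5811731
6,Shut Up and Dance,Walk the Moon,200,98.47,5034637
7,Blank Space,Taylor Swift,232,98.11,6764128
8,Watch Me,Silento,186,96.99,4463863
9,Earned It (Fifty Shades of Grey),The Weeknd,252,98.66,7514440
10,The Hills,The Weeknd,243,99.08,8657473
11,Cheerleader (Felix Jaehn Remix),OMI,182,96.84,17933224
12,Can't Feel My Face,The Weeknd,214,99.34,8675375
13,Love Me Like You Do,Ellie Goulding,251,99.56,9925090
14,Take Me to Church,Hozier,242,98.82,15854482
16,Lean On,Major Lazer & DJ Snake Feat. M0,177,99.10,19974795
17,Want to Want Me,Jason Derulo,208,98.89,9885505
18,Shake It Off,Taylor Swift,220,95.90,3162707
19,Where Are U Now,Skrillex & Diplo with Justin Bieber,251,99.44,7639899
20,Fight Song,Rachel Platten,205,99.23,4359870
21,679,Fetty Wap Feat. Remy Boyz,197,98.71,3020785
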